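#' Read dose-response records from CSV
#'
#' The expected record format is one observation per line:
#' `compound name, channel name, experiment number, dose (uM),
#' response (% inhibition)`. A header line is optional and detected
#' automatically (a first line whose dose/response fields are not numeric).
#' Responses outside \[0, 100\] are capped to the nearest bound with a
#' warning, mirroring how raw screening data are capped before analysis;
#' the truncated observation model accounts for this.
#'
#' @param path Path to a CSV file.
#' @param compound,channel Optional filters; required when the file holds
#'   more than one compound/channel combination.
#' @return A [dose_response_data()] object.
#' @export
read_dose_response <- function(path, compound = NULL, channel = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("no records in ", path)
  first <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  # a header has text where the numeric fields belong (experiment number
  # too, so a data row with one bad field is still reported as an error)
  non_num <- function(v) is.na(suppressWarnings(as.numeric(trimws(v))))
  has_header <- length(first) >= 5 && non_num(first[3]) &&
    (non_num(first[4]) || non_num(first[5]))
  rows <- if (has_header) lines[-1] else lines
  offset <- if (has_header) 1L else 0L
  if (length(rows) == 0) stop("no records in ", path)

  parts <- strsplit(rows, ",", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 5)) {
    bad <- which(nf != 5)[1]
    stop(sprintf(paste0("line %d: expected 5 comma-separated fields ",
                        "(compound, channel, experiment number, dose, ",
                        "response), found %d"),
                 bad + offset, nf[bad]))
  }
  m <- matrix(trimws(unlist(parts)), ncol = 5, byrow = TRUE)
  num_field <- function(col, what) {
    v <- suppressWarnings(as.numeric(m[, col]))
    if (any(is.na(v))) {
      bad <- which(is.na(v))[1]
      stop(sprintf("line %d: field '%s' is not numeric (got '%s')",
                   bad + offset, what, m[bad, col]))
    }
    v
  }
  expn <- num_field(3, "experiment number")
  if (any(expn != round(expn)) || any(expn < 1)) {
    stop("experiment numbers must be positive integers")
  }
  dose <- num_field(4, "dose (uM)")
  resp <- num_field(5, "response (% inhibition)")

  keep <- rep(TRUE, nrow(m))
  if (!is.null(compound)) keep <- keep & m[, 1] == compound
  if (!is.null(channel)) keep <- keep & m[, 2] == channel
  if (!any(keep)) stop("no records remain after filtering on compound/channel")
  m <- m[keep, , drop = FALSE]
  expn <- expn[keep]; dose <- dose[keep]; resp <- resp[keep]

  combos <- unique(paste(m[, 1], m[, 2], sep = " / "))
  if (length(combos) > 1) {
    stop("file contains multiple compound/channel combinations (",
         paste(combos, collapse = "; "),
         "); use the 'compound' and 'channel' filters")
  }
  n_cap <- sum(resp < 0 | resp > 100)
  if (n_cap > 0) {
    warning(sprintf("capped %d response value(s) into [0, 100]", n_cap))
    resp <- pmin(pmax(resp, 0), 100)
  }
  dose_response_data(expn, dose, resp,
                     compound = m[1, 1], channel = m[1, 2])
}

#' Write a dose-response dataset in the standard record format
#'
#' @param data A [dose_response_data()] object.
#' @param path Output CSV path.
#' @param header Write a header line (default TRUE).
#' @return `path`, invisibly.
#' @export
write_dose_response <- function(data, path, header = TRUE) {
  stopifnot(inherits(data, "dose_response_data"))
  lines <- sprintf("%s,%s,%d,%s,%s",
                   attr(data, "compound"), attr(data, "channel"),
                   data$experiment,
                   fmt_full(data$dose), fmt_full(data$response))
  if (header) {
    lines <- c("compound,channel,experiment,dose_uM,response_percent", lines)
  }
  writeLines(lines, path)
  invisible(path)
}

# shortest decimal representation that round-trips a double
fmt_full <- function(x) sprintf("%.17g", x)

#' Write and read posterior chains as CSV
#'
#' `write_chain()` stores one named column per parameter plus the
#' log-posterior, at full double precision so that reading the file back
#' reproduces the chain exactly. `read_chain()` restores a
#' `posterior_chain` (metadata limited to what the file holds).
#'
#' @param chain A `posterior_chain`.
#' @param path CSV path.
#' @return `write_chain()` returns `path` invisibly; `read_chain()` a
#'   `posterior_chain`.
#' @export
write_chain <- function(chain, path) {
  stopifnot(inherits(chain, "posterior_chain"))
  if (nrow(chain$samples) == 0) stop("chain contains no samples")
  m <- cbind(chain$samples, log_posterior = chain$log_posterior)
  txt <- apply(m, 1, function(r) paste(fmt_full(r), collapse = ","))
  ok <- tryCatch({
    writeLines(c(paste(colnames(m), collapse = ","), txt), path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("could not write chain to ", path)
  invisible(path)
}

#' @rdname write_chain
#' @export
read_chain <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"log_posterior" %in% names(df)) {
    stop("not a chain file (no 'log_posterior' column): ", path)
  }
  lp <- df$log_posterior
  sm <- as.matrix(df[setdiff(names(df), "log_posterior")])
  structure(list(samples = sm, log_posterior = lp,
                 accepted = rep(NA, nrow(sm)),
                 meta = list(source = path, n_iter = nrow(sm),
                             d = ncol(sm), par_names = colnames(sm),
                             acceptance_rate = NA_real_)),
            class = "posterior_chain")
}

#' Percent-block prediction samples at a concentration
#'
#' Pushes posterior `(pIC50, Hill)` samples through the Hill curve at a
#' fixed concentration, yielding a sample of percent-block values — the
#' vertical cross-section through the fan of posterior dose-response
#' curves. Three sources of samples are supported: the columns of a
#' single-level chain; the top-level `(mu, alpha)` columns of a
#' hierarchical chain ("underlying" effect, inter-experiment variability
#' discounted); or draws from the posterior-predictive distributions
#' ("future experiment", variability included). `predict_block()` is the
#' low-level worker taking an explicit sample matrix;
#' [chain_block_samples()] extracts the appropriate columns from a chain.
#'
#' @param samples Matrix or data.frame whose first two columns (or columns
#'   named `pIC50` and `Hill`) hold the sample pairs.
#' @param concentration Dose in micromolar, `> 0`.
#' @param source Label recorded on the result (`"single-level"`,
#'   `"hierarchical-underlying"` or `"hierarchical-predictive"`).
#' @return An object of class `block_prediction`: list with
#'   `concentration`, `block_samples` (percent block, in `[0, 100]`) and
#'   `source`.
#' @export
predict_block <- function(samples, concentration, source = "single-level") {
  sm <- as.matrix(samples)
  if (is.null(dim(sm)) || nrow(sm) < 1 || ncol(sm) < 2) {
    stop("'samples' must contain at least one (pIC50, Hill) pair")
  }
  if (!is.finite(concentration) || concentration <= 0) {
    stop("'concentration' must be a positive dose in uM")
  }
  cols <- colnames(sm)
  if (!is.null(cols) && all(c("pIC50", "Hill") %in% cols)) {
    sm <- sm[, c("pIC50", "Hill"), drop = FALSE]
  } else {
    sm <- sm[, 1:2, drop = FALSE]
  }
  structure(list(concentration = concentration,
                 block_samples = hill_response(concentration, sm[, 1], sm[, 2]),
                 source = source),
            class = "block_prediction")
}

#' @rdname predict_block
#' @param chain A `posterior_chain` (burned), single-level or hierarchical.
#' @param mode `"single"`, `"underlying"` or `"predictive"`.
#' @param n Number of predictive draws (`"predictive"` mode only; default:
#'   number of retained iterations).
#' @param seed Seed for predictive draws.
#' @export
chain_block_samples <- function(chain, concentration,
                                mode = c("single", "underlying", "predictive"),
                                n = NULL, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(chain, "posterior_chain"))
  sm <- chain$samples
  if (mode == "single") {
    if (!all(c("pIC50", "Hill") %in% colnames(sm))) {
      stop("mode 'single' needs a single-level chain with pIC50/Hill columns")
    }
    predict_block(sm[, c("pIC50", "Hill")], concentration, "single-level")
  } else if (mode == "underlying") {
    if (!all(c("mu", "alpha") %in% colnames(sm))) {
      stop("mode 'underlying' needs a hierarchical chain with mu/alpha columns")
    }
    m <- cbind(pIC50 = sm[, "mu"], Hill = sm[, "alpha"])
    predict_block(m, concentration, "hierarchical-underlying")
  } else {
    if (is.null(n)) n <- nrow(sm)
    seeds <- derive_seeds(seed, 2)
    p_draw <- sample_predictive(posterior_predictive(chain, "pIC50"), n,
                                seed = seeds[[1]])
    h_draw <- sample_predictive(posterior_predictive(chain, "Hill"), n,
                                seed = seeds[[2]])
    predict_block(cbind(pIC50 = p_draw, Hill = h_draw), concentration,
                  "hierarchical-predictive")
  }
}

#' Write a complete fit to an output directory
#'
#' Creates `dir` (if needed) and writes `chain.csv` (full-precision
#' samples), `summary.csv` (posterior mean, sd, median and central 95%
#' interval per parameter) and `run_info.txt` (plain key-value metadata:
#' model, seed, iterations, burn-in fraction, acceptance rate).
#'
#' @param chain A `posterior_chain` from [fit_single_level()] or
#'   [fit_hierarchical()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_fit <- function(chain, dir) {
  stopifnot(inherits(chain, "posterior_chain"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_chain(chain, file.path(dir, "chain.csv"))
  utils::write.csv(summary(chain), file.path(dir, "summary.csv"),
                   row.names = FALSE)
  meta <- chain$meta
  kv <- c(model = meta$model %||% "unknown",
          compound = meta$compound %||% "unknown",
          channel = meta$channel %||% "unknown",
          seed = meta$master_seed %||% meta$seed %||% "none",
          iterations = meta$n_iter,
          burn_fraction = meta$burn_fraction,
          retained_samples = nrow(chain$samples),
          acceptance_rate = sprintf("%.4f", meta$acceptance_rate))
  writeLines(paste(names(kv), unname(kv), sep = " = "),
             file.path(dir, "run_info.txt"))
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
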