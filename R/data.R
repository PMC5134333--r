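#' Dose-response dataset for one compound/channel pair
#'
#' A light container for screening records: one row per observation with the
#' experimental repeat it came from, the applied dose in micromolar and the
#' measured response in percent block. All records belong to a single
#' compound and channel; multi-compound files must be filtered on ingest
#' (see [read_dose_response()]).
#'
#' @param experiment Integer vector of positive experiment (repeat) labels.
#' @param dose Numeric vector of concentrations in micromolar, `>= 0`.
#' @param response Numeric vector of percent block values in `[0, 100]`.
#' @param compound,channel Single character labels.
#' @return An object of class `dose_response_data`: a `data.frame` with
#'   columns `experiment`, `dose`, `response` and attributes `compound` and
#'   `channel`. Experiments are additionally indexed 1..Ne in column
#'   `exp_index` (order of first appearance).
#' @examples
#' d <- dose_response_data(experiment = c(1, 1, 2, 2),
#'                         dose = c(0.1, 1, 0.1, 1),
#'                         response = c(9, 52, 11, 48),
#'                         compound = "drugA", channel = "hERG")
#' n_experiments(d)
#' @export
dose_response_data <- function(experiment, dose, response,
                               compound = "unknown", channel = "unknown") {
  if (length(dose) < 1) stop("dataset must contain at least one record")
  if (length(experiment) != length(dose) || length(response) != length(dose)) {
    stop("'experiment', 'dose' and 'response' must have equal length")
  }
  experiment <- as.integer(experiment)
  if (any(is.na(experiment)) || any(experiment < 1)) {
    stop("'experiment' labels must be positive integers")
  }
  if (any(!is.finite(dose)) || any(dose < 0)) {
    stop("'dose' must be non-negative and finite (uM)")
  }
  if (any(!is.finite(response)) || any(response < 0) || any(response > 100)) {
    stop("'response' must lie in [0, 100] percent block; cap on ingest")
  }
  ids <- unique(experiment)
  df <- data.frame(
    experiment = experiment,
    dose = as.numeric(dose),
    response = as.numeric(response),
    exp_index = match(experiment, ids)
  )
  attr(df, "compound") <- as.character(compound)[1]
  attr(df, "channel") <- as.character(channel)[1]
  class(df) <- c("dose_response_data", "data.frame")
  df
}

#' @rdname dose_response_data
#' @param x A `dose_response_data` object.
#' @export
n_experiments <- function(x) {
  stopifnot(inherits(x, "dose_response_data"))
  max(x$exp_index)
}

#' @rdname dose_response_data
#' @export
n_records <- function(x) {
  stopifnot(inherits(x, "dose_response_data"))
  nrow(x)
}

#' @param ... Unused.
#' @rdname dose_response_data
#' @export
print.dose_response_data <- function(x, ...) {
  cat(sprintf("Dose-response data: %s on %s\n",
              attr(x, "compound"), attr(x, "channel")))
  cat(sprintf("  %d records across %d experiment(s)\n",
              nrow(x), n_experiments(x)))
  print.data.frame(x, ...)
  invisible(x)
}
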