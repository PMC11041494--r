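#' Right-censored survival dataset
#'
#' Container for one site's survival data: a numeric feature matrix, strictly
#' positive survival times (days), and binary event indicators. Times are
#' natural-log-transformed once, at construction; the model and all residuals
#' live on the log-time scale.
#'
#' @param features numeric matrix (n x p) or data.frame of numeric columns.
#' @param times strictly positive survival or censoring times, in days.
#' @param events event indicators: 1/TRUE = event observed, 0/FALSE = censored.
#' @param feature_names optional column labels; defaults to the matrix
#'   colnames or `x1..xp`.
#' @param sample_ids optional row labels; defaults to rownames or `1..n`.
#'
#' @return an object of class `survival_dataset` with fields `features`,
#'   `times`, `log_times`, `events`, `feature_names`, `sample_ids`.
#' @export
survival_dataset <- function(features, times, events,
                             feature_names = NULL, sample_ids = NULL) {
  if (is.data.frame(features)) {
    bad <- !vapply(features, is.numeric, logical(1))
    if (any(bad)) {
      stop_invalid("non-numeric feature column(s): ",
                   paste(names(features)[bad], collapse = ", "))
    }
    features <- as.matrix(features)
  }
  if (!is.matrix(features) || !is.numeric(features)) {
    stop_invalid("features must be a numeric matrix or data.frame")
  }
  n <- nrow(features)
  p <- ncol(features)
  if (p < 1L) stop_invalid("need p >= 1 features")
  if (length(times) != n || length(events) != n) {
    stop_invalid("times/events length must equal nrow(features)")
  }
  if (anyNA(features) || anyNA(times) || anyNA(events)) {
    stop_invalid("missing values are not allowed after preprocessing")
  }
  if (any(times <= 0)) {
    stop_invalid("all survival times must be strictly positive; offending rows: ",
                 paste(utils::head(which(times <= 0), 5L), collapse = ", "))
  }
  events <- as.numeric(events)
  if (!all(events %in% c(0, 1))) {
    stop_invalid("event indicators must be binary (0/1 or TRUE/FALSE)")
  }
  feature_names <- feature_names %||% colnames(features) %||% paste0("x", seq_len(p))
  sample_ids <- as.character(sample_ids %||% rownames(features) %||% seq_len(n))
  dimnames(features) <- list(NULL, feature_names)
  structure(
    list(features = features, times = as.numeric(times),
         log_times = log(as.numeric(times)), events = events,
         feature_names = feature_names, sample_ids = sample_ids),
    class = "survival_dataset")
}

#' @export
print.survival_dataset <- function(x, ...) {
  cat(sprintf("<survival_dataset> n = %d, p = %d, events = %d (%.1f%% censored)\n",
              length(x$times), ncol(x$features), sum(x$events),
              100 * mean(1 - x$events)))
  invisible(x)
}

#' @export
dim.survival_dataset <- function(x) dim(x$features)

#' Subset a survival dataset by row
#'
#' @param data a [survival_dataset()].
#' @param idx integer or logical row index; all parallel fields stay aligned.
#' @return the row-subset [survival_dataset()].
#' @export
dataset_subset <- function(data, idx) {
  survival_dataset(data$features[idx, , drop = FALSE], data$times[idx],
                   data$events[idx], feature_names = data$feature_names,
                   sample_ids = data$sample_ids[idx])
}

check_same_schema <- function(datasets) {
  ref <- datasets[[1L]]$feature_names
  for (k in seq_along(datasets)) {
    if (!identical(datasets[[k]]$feature_names, ref)) {
      stop_protocol("clients disagree on feature schema (client ", k,
                    "); horizontal federation requires identical columns")
    }
  }
  invisible(ref)
}
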