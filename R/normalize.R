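# Federated z-score normalization. Each client shares only (n, column sums,
# column sums of squares); the coordinator combines them into global
# mean/std, which equal the pooled-data statistics exactly because the
# moment decomposition is additive. Population (divide-by-n) variance is
# used so the decomposition is exact.

#' Per-client feature moments
#'
#' @param data a [survival_dataset()] or numeric matrix.
#' @return list with `n`, `sum`, `sum_sq` (per feature) — the only
#'   statistics a client needs to reveal for global normalization; all three
#'   are additive and can be exchanged through [secure_sum()].
#' @export
local_moments <- function(data) {
  X <- if (inherits(data, "survival_dataset")) data$features else data
  if (!is.numeric(X)) stop_invalid("features must be numeric")
  list(n = nrow(X), sum = colSums(X), sum_sq = colSums(X^2))
}

#' Combine client moments into global normalization statistics
#'
#' @param summaries list of [local_moments()] results.
#' @return list with `mean`, `std` (population convention), and `constant`,
#'   a logical flag per feature; constant features get `std = 1` so they map
#'   to exact zeros instead of NaN.
#' @export
global_normalization <- function(summaries) {
  n <- sum(vapply(summaries, `[[`, 0, "n"))
  if (n < 2) stop_invalid("need at least 2 pooled samples to normalize")
  s1 <- Reduce(`+`, lapply(summaries, `[[`, "sum"))
  s2 <- Reduce(`+`, lapply(summaries, `[[`, "sum_sq"))
  mu <- s1 / n
  v <- pmax(s2 / n - mu^2, 0)
  constant <- v < .Machine$double.eps * pmax(1, mu^2)
  std <- sqrt(v)
  std[constant] <- 1
  list(mean = mu, std = std, constant = constant, n = n)
}

#' Apply or invert z-score normalization
#'
#' @param data a [survival_dataset()] or numeric matrix.
#' @param stats a [global_normalization()] result.
#' @return the same kind of object with features replaced by
#'   `(x - mean) / std` (or the inverse).
#' @export
apply_normalization <- function(data, stats) {
  transform_features(data, function(X)
    sweep(sweep(X, 2, stats$mean, "-"), 2, stats$std, "/"))
}

#' @rdname apply_normalization
#' @export
invert_normalization <- function(data, stats) {
  transform_features(data, function(X)
    sweep(sweep(X, 2, stats$std, "*"), 2, stats$mean, "+"))
}

transform_features <- function(data, f) {
  if (inherits(data, "survival_dataset")) {
    survival_dataset(f(data$features), data$times, data$events,
                     feature_names = data$feature_names,
                     sample_ids = data$sample_ids)
  } else {
    f(data)
  }
}
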