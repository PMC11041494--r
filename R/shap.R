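# Shapley attributions for a linear model have a closed form: with
# background mean mu, feature j of sample i contributes
# phi_ij = w_j * (x_ij - mu_j), and sum_j phi_ij + (w'mu + b) equals the
# model's prediction exactly (local accuracy). The background mean should be
# the (federated) training mean, which after z-score normalization is ~0.

#' Linear SHAP attributions
#'
#' @param model a `survsvm` fit or `list(weights=, intercept=)`.
#' @param features numeric matrix (m x p), a data.frame of numeric columns,
#'   or a [survival_dataset()].
#' @param background_mean length-p baseline feature vector, normally the
#'   training-data mean; defaults to zeros (the mean of z-scored features).
#' @return object of class `shap_attribution`: `phi` (m x p matrix),
#'   `base_value` = `w' mu + b`.
#' @export
linear_shap <- function(model, features, background_mean = NULL) {
  m <- as_model_params(model)
  if (inherits(features, "survival_dataset")) features <- features$features
  features <- as.matrix(features)
  check_model_dim(m, ncol(features))
  mu <- background_mean %||% numeric(ncol(features))
  if (length(mu) != ncol(features)) {
    stop_invalid("background_mean length must equal the number of features")
  }
  phi <- sweep(features, 2, mu, "-") %*% diag(m$weights, length(m$weights))
  dimnames(phi) <- dimnames(features)
  structure(list(phi = phi, base_value = sum(m$weights * mu) + m$intercept),
            class = "shap_attribution")
}

#' @export
print.shap_attribution <- function(x, ...) {
  cat(sprintf("<shap_attribution> %d samples x %d features, base value %.4f\n",
              nrow(x$phi), ncol(x$phi), x$base_value))
  cat("Mean |phi| per feature:\n")
  print(round(colMeans(abs(x$phi)), 4))
  invisible(x)
}

#' Pearson correlation of two attribution matrices
#'
#' Used to compare the explanations of two models (e.g. central vs
#' federated) on a shared test set: the correlation of the flattened
#' attribution matrices.
#'
#' @param a,b `shap_attribution` objects of identical shape.
#' @return Pearson correlation in `[-1, 1]`.
#' @export
shap_correlation <- function(a, b) {
  pa <- if (inherits(a, "shap_attribution")) a$phi else as.matrix(a)
  pb <- if (inherits(b, "shap_attribution")) b$phi else as.matrix(b)
  if (!all(dim(pa) == dim(pb))) stop_invalid("attribution shapes differ")
  va <- as.numeric(pa)
  vb <- as.numeric(pb)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    stop_undefined("attribution correlation undefined: zero variance")
  }
  stats::cor(va, vb)
}
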