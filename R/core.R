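# Core survival-SVM regression objective (rank ratio 0).
#
# Per-sample loss term (zeta residual), on the log-time scale:
#   event    (delta = 1): zeta_i = log y_i - (w'x_i + b)
#   censored (delta = 0): zeta_i = max(0, log y_i - (w'x_i + b))
# A censored observation is a lower bound on the true time, so it is
# penalized only when the model under-predicts it.
#
# Objective: f(b, w) = 1/2 ||w||^2 + alpha/2 * sum_i zeta_i^2.
# The intercept b is not regularized. The gradient and Hessian of the loss
# part are over (b, w) jointly; a censored sample with zeta_i = 0 contributes
# nothing (subgradient 0 at the hinge kink).

#' Control parameters for survival-SVM fitting
#'
#' @param alpha positive loss weight; the regularizer `||w||^2/2` is fixed,
#'   so smaller `alpha` means stronger shrinkage. Default 1e-4.
#' @param fit_intercept fit an unregularized intercept on the log-time scale.
#' @param max_iter maximum number of Newton rounds.
#' @param grad_tol convergence threshold on the infinity norm of the global
#'   gradient.
#' @param cg_tol relative residual tolerance of the conjugate-gradient solve
#'   of each Newton system.
#'
#' @return a list of validated hyperparameters, class `svm_control`.
#' @export
svm_control <- function(alpha = 1e-4, fit_intercept = TRUE, max_iter = 50L,
                        grad_tol = 1e-5, cg_tol = 1e-8) {
  if (alpha <= 0) stop_invalid("alpha must be > 0")
  if (max_iter < 1L) stop_invalid("max_iter must be >= 1")
  if (grad_tol <= 0 || cg_tol <= 0) stop_invalid("tolerances must be > 0")
  structure(list(alpha = alpha, rank_ratio = 0,
                 fit_intercept = isTRUE(fit_intercept),
                 max_iter = as.integer(max_iter),
                 grad_tol = grad_tol, cg_tol = cg_tol),
            class = "svm_control")
}

# Accept a survsvm fit or a bare list(weights, intercept).
as_model_params <- function(model) {
  if (inherits(model, "survsvm")) {
    list(weights = unname(model$coefficients), intercept = model$intercept %||% 0)
  } else {
    list(weights = as.numeric(model$weights),
         intercept = as.numeric(model$intercept %||% 0))
  }
}

check_model_dim <- function(model, p) {
  if (length(model$weights) != p) {
    stop_invalid("model has ", length(model$weights),
                 " weights but data has ", p, " features")
  }
}

#' Zeta residuals of a survival SVM
#'
#' Full residual `log(t) - prediction` for event samples; hinge-clipped
#' residual `max(0, log(t) - prediction)` for censored samples.
#'
#' @param model a fitted `survsvm` object or a `list(weights=, intercept=)`.
#' @param data a [survival_dataset()].
#' @return numeric vector of length n.
#' @export
zeta_residuals <- function(model, data) {
  m <- as_model_params(model)
  check_model_dim(m, ncol(data$features))
  raw <- data$log_times - drop(data$features %*% m$weights) - m$intercept
  ifelse(data$events == 1, raw, pmax(0, raw))
}

#' Survival-SVM objective value
#'
#' `||w||^2/2 + alpha/2 * sum(zeta^2)`; the intercept is not regularized.
#'
#' @inheritParams zeta_residuals
#' @param control an [svm_control()] list (only `alpha` is used).
#' @return scalar objective value.
#' @export
svm_objective <- function(model, data, control = svm_control()) {
  m <- as_model_params(model)
  z <- zeta_residuals(model, data)
  0.5 * sum(m$weights^2) + 0.5 * control$alpha * sum(z^2)
}

#' One client's contribution to the global Newton system
#'
#' Computes the loss part of the objective, gradient, and Hessian at the
#' current model, over `(b, w)` jointly when an intercept is fitted. The
#' `||w||^2/2` regularizer is excluded: the coordinator adds it exactly once
#' after summation, so that summing `local_summary` objects over any
#' horizontal partition reproduces the centralized quantities.
#'
#' @inheritParams svm_objective
#' @return list with `objective_part` (scalar), `gradient` (length p+1 with
#'   intercept first, else length p), `hessian` (matching square matrix),
#'   `n_samples`, `n_active`.
#' @export
local_summary <- function(model, data, control = svm_control()) {
  m <- as_model_params(model)
  check_model_dim(m, ncol(data$features))
  theta <- if (control$fit_intercept) c(m$intercept, m$weights) else m$weights
  X1 <- design_matrix(data$features, control$fit_intercept)
  loss_parts(theta, X1, data$log_times, data$events, control$alpha)
}

design_matrix <- function(X, fit_intercept) {
  if (fit_intercept) cbind(rep(1, nrow(X)), X, deparse.level = 0) else X
}

# theta = (b, w) if the design has an intercept column; loss part only.
loss_parts <- function(theta, X1, logy, events, alpha) {
  zeta <- logy - drop(X1 %*% theta)
  active <- events == 1 | zeta > 0
  za <- zeta[active]
  Xa <- X1[active, , drop = FALSE]
  list(objective_part = 0.5 * alpha * sum(za^2),
       gradient = unname(-alpha * drop(crossprod(Xa, za))),
       hessian = unname(alpha * crossprod(Xa)),
       n_samples = length(logy),
       n_active = sum(active))
}

# Linear predictor on the log-time scale.
linear_predict <- function(weights, intercept, features) {
  if (ncol(features) != length(weights)) {
    stop_invalid("newdata has ", ncol(features), " features; model expects ",
                 length(weights))
  }
  drop(features %*% weights) + intercept
}
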