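#' Survival support vector machine, centralized or federated
#'
#' Fits a linear survival SVM with the regression objective
#' \deqn{\min_{w,b} \tfrac12 \|w\|^2 + \tfrac{\alpha}{2} \sum_i \zeta_i^2,}
#' where \eqn{\zeta_i = \log y_i - (w^\top x_i + b)} for samples with an
#' observed event and \eqn{\zeta_i = \max(0, \log y_i - (w^\top x_i + b))}
#' for right-censored samples, optimized by truncated Newton (Newton-CG).
#' When `clients` is supplied the rows are partitioned across simulated
#' sites and the model is fitted federatedly — sites exchange only summed
#' objective/gradient/Hessian contributions (optionally masked by additive
#' secret sharing) — yielding the same solution as pooling the data.
#'
#' Predictions are on the log-time scale: larger values mean longer
#' predicted survival, i.e. lower risk.
#'
#' @param formula a formula with a `survival::Surv(time, event)` left-hand
#'   side; factor covariates are expanded to indicator columns.
#' @param data data frame holding the variables.
#' @param clients optional vector/factor with one site label per row; `NULL`
#'   fits on pooled data (single site).
#' @param alpha positive loss weight \eqn{\alpha} (default 1e-4).
#' @param fit_intercept fit an unregularized intercept (default TRUE).
#' @param max_iter maximum Newton rounds (default 50).
#' @param grad_tol,cg_tol convergence tolerances, see [svm_control()].
#' @param smpc mask every exchanged aggregate with additive secret sharing.
#' @param codec fixed-point codec used when `smpc = TRUE`.
#' @param seed seed for the shard randomness (ignored unless `smpc = TRUE`).
#' @param keep_data keep the assembled pooled dataset on the object (needed
#'   by [residuals.survsvm()] without a `data` argument).
#'
#' @return an object of class `survsvm` with components `coefficients`,
#'   `intercept`, `converged`, `n_iterations`, `final_objective`, `rounds`
#'   (per-round optimization log), `n_clients`, and the usual `call`/`terms`.
#'
#' @examples
#' d <- generate_survival(n = 200, p = 4, seed = 1)
#' df <- as.data.frame(d)
#' fit <- survsvm(survival::Surv(time, event) ~ ., data = df)
#' coef(fit)
#' head(predict(fit, df))
#' @seealso [fit_federated()], [fit_central()], [harrell_cindex()]
#' @export
survsvm <- function(formula, data, clients = NULL, alpha = 1e-4,
                    fit_intercept = TRUE, max_iter = 50L, grad_tol = 1e-5,
                    cg_tol = 1e-8, smpc = FALSE, codec = fp_codec(),
                    seed = NULL, keep_data = TRUE) {
  control <- svm_control(alpha = alpha, fit_intercept = fit_intercept,
                         max_iter = max_iter, grad_tol = grad_tol,
                         cg_tol = cg_tol)
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (!inherits(y, "Surv")) {
    stop_invalid("the response must be a survival::Surv(time, event) object")
  }
  if (attr(y, "type") != "right") {
    stop_invalid("only right-censored responses are supported")
  }
  mt <- attr(mf, "terms")
  attr(mt, "intercept") <- 1L  # intercept handled internally, not as a column
  X <- stats::model.matrix(mt, mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  ds <- survival_dataset(X, times = y[, "time"], events = y[, "status"])

  if (is.null(clients)) {
    parts <- list(ds)
  } else {
    if (length(clients) != nrow(X)) {
      stop_invalid("clients must have one label per row of data")
    }
    parts <- lapply(split(seq_len(nrow(X)), clients), function(i)
      dataset_subset(ds, i))
  }
  fit <- fit_federated(parts, control = control, use_smpc = smpc,
                       codec = codec, seed = seed)
  fit$call <- match.call()
  fit$terms <- mt
  fit$xlevels <- stats::.getXlevels(mt, mf)
  if (keep_data) fit$data <- ds
  fit
}

#' @export
print.survsvm <- function(x, digits = max(3L, getOption("digits") - 3L), ...) {
  cat("Survival SVM (regression objective, rank ratio 0)\n")
  if (!is.null(x$call)) {
    cat("Call: ", paste(deparse(x$call), collapse = "\n"), "\n", sep = "")
  }
  cat(sprintf("%d client%s, n = %d, alpha = %g, %s after %d Newton round%s\n",
              x$n_clients, if (x$n_clients == 1L) "" else "s",
              sum(x$n_samples), x$control$alpha,
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations, if (x$n_iterations == 1L) "" else "s"))
  if (x$use_smpc) cat("Aggregation: additive secret sharing (SMPC)\n")
  cat("Coefficients (log-time scale):\n")
  cf <- c("(Intercept)" = x$intercept, x$coefficients)
  if (!x$control$fit_intercept) cf <- x$coefficients
  print(round(cf, digits))
  invisible(x)
}

#' @export
coef.survsvm <- function(object, ...) {
  if (object$control$fit_intercept) {
    c("(Intercept)" = object$intercept, object$coefficients)
  } else {
    object$coefficients
  }
}

#' Summarize a fitted survival SVM
#'
#' The absolute weight of each (normalized) feature doubles as a feature
#' importance measure for the linear model.
#'
#' @param object a `survsvm` fit.
#' @param ... unused.
#' @export
summary.survsvm <- function(object, ...) {
  tab <- data.frame(weight = object$coefficients,
                    abs_weight = abs(object$coefficients))
  tab <- tab[order(-tab$abs_weight), ]
  structure(list(fit = object, importance = tab), class = "summary.survsvm")
}

#' @export
print.summary.survsvm <- function(x, digits = 4L, ...) {
  print(x$fit)
  cat("\nFeature importance (|weight|, descending):\n")
  print(round(x$importance, digits))
  if (!is.null(x$fit$rounds) && nrow(x$fit$rounds) > 0L) {
    fr <- x$fit$rounds
    cat(sprintf("\nFinal objective %.6g; last round gradient norm %.3g\n",
                x$fit$final_objective,
                fr$global_grad_norm[nrow(fr)]))
  }
  invisible(x)
}

#' Predict from a survival SVM
#'
#' @param object a `survsvm` fit.
#' @param newdata data frame (formula fits), numeric feature matrix, or
#'   [survival_dataset()]. Defaults to the stored training data.
#' @param type `"logtime"` (linear predictor, the default), `"time"`
#'   (exponentiated), or `"risk"` (negated log-time, for concordance:
#'   higher = earlier expected event).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.survsvm <- function(object, newdata = NULL,
                            type = c("logtime", "time", "risk"), ...) {
  type <- match.arg(type)
  X <- resolve_features(object, newdata)
  lp <- linear_predict(object$coefficients, object$intercept, X)
  switch(type, logtime = lp, time = exp(lp), risk = -lp)
}

resolve_features <- function(object, newdata) {
  if (is.null(newdata)) {
    if (is.null(object$data)) {
      stop_invalid("no stored training data; supply newdata")
    }
    return(object$data$features)
  }
  if (inherits(newdata, "survival_dataset")) return(newdata$features)
  if (is.matrix(newdata)) return(newdata)
  if (is.data.frame(newdata) && !is.null(object$terms)) {
    tt <- stats::delete.response(object$terms)
    mf <- stats::model.frame(tt, newdata, xlev = object$xlevels)
    X <- stats::model.matrix(tt, mf)
    return(X[, colnames(X) != "(Intercept)", drop = FALSE])
  }
  if (is.data.frame(newdata)) return(as.matrix(newdata))
  stop_invalid("newdata must be a data frame, matrix, or survival_dataset")
}

#' Zeta residuals of a fit
#'
#' @param object a `survsvm` fit.
#' @param data optional [survival_dataset()]; defaults to the stored
#'   training data.
#' @param ... unused.
#' @export
residuals.survsvm <- function(object, data = NULL, ...) {
  data <- data %||% object$data
  if (is.null(data)) stop_invalid("no stored training data; supply data")
  zeta_residuals(object, data)
}
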