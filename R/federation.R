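# Simulated horizontal federation: clients expose closures that evaluate
# local sufficient statistics at a broadcast parameter vector; the
# coordinator sees only aggregates (summed objective / gradient / Hessian),
# never any client's data. Summation is pluggable: plain elementwise sums or
# the additive-secret-sharing protocol in smpc.R.

# A client is a closure interface over its private dataset. Coordinator code
# must only ever call these functions.
fs_client <- function(data, control, client_id = NULL) {
  X1 <- design_matrix(data$features, control$fit_intercept)
  logy <- data$log_times
  events <- data$events
  alpha <- control$alpha
  list(
    client_id = client_id %||% "client",
    dim = function() ncol(X1),
    n = function() length(logy),
    n_events = function() sum(events),
    # (n, sum of log-times): enough for the coordinator's intercept start.
    time_moments = function() c(length(logy), sum(logy)),
    summary_at = function(theta) {
      if (length(logy) == 0L) {
        d <- ncol(X1)
        return(list(objective_part = 0, gradient = numeric(d),
                    hessian = matrix(0, d, d), n_samples = 0L, n_active = 0L))
      }
      loss_parts(theta, X1, logy, events, alpha)
    },
    objective_at = function(theta) {
      if (length(logy) == 0L) return(0)
      zeta <- logy - drop(X1 %*% theta)
      zeta[events == 0] <- pmax(0, zeta[events == 0])
      0.5 * alpha * sum(zeta^2)
    })
}

# Aggregation backend. sum_tensors() takes a list with one tensor per client.
make_aggregator <- function(use_smpc = FALSE, codec = fp_codec()) {
  messages <- 0
  sum_tensors <- if (use_smpc) {
    function(values) {
      out <- secure_sum(values, codec)
      messages <<- messages + attr(out, "messages")
      attr(out, "messages") <- NULL
      out
    }
  } else {
    function(values) {
      messages <<- messages + length(values)
      Reduce(`+`, values)
    }
  }
  list(sum_tensors = sum_tensors, message_count = function() messages,
       secure = use_smpc)
}

# Regularizer ||w||^2 / 2, added exactly once, coordinator-side. theta is
# (b, w) when an intercept is fitted; b is never penalized.
regularizer <- function(theta, fit_intercept) {
  w <- if (fit_intercept) theta[-1L] else theta
  mask <- if (fit_intercept) c(0, rep(1, length(w))) else rep(1, length(w))
  list(objective = 0.5 * sum(w^2),
       gradient = mask * theta,
       hessian = diag(mask, nrow = length(theta)))
}

#' Aggregate per-client summaries into the global Newton system
#'
#' Sums the clients' loss contributions elementwise and adds the
#' `||w||^2 / 2` regularizer exactly once. With a single client the result
#' equals the centralized objective, gradient, and Hessian bit for bit.
#'
#' @param summaries list of [local_summary()] results, one per client, all
#'   evaluated at the same model.
#' @param model the model they were evaluated at (`survsvm` or
#'   `list(weights=, intercept=)`).
#' @param control an [svm_control()].
#' @return list with `objective`, `gradient`, `hessian`, `n_samples`.
#' @export
aggregate_summaries <- function(summaries, model, control = svm_control()) {
  if (length(summaries) < 1L) stop_protocol("no client summaries to aggregate")
  d <- length(summaries[[1L]]$gradient)
  for (s in summaries) {
    if (length(s$gradient) != d || !all(dim(s$hessian) == d)) {
      stop_protocol("client summaries disagree in dimension")
    }
  }
  m <- as_model_params(model)
  theta <- if (control$fit_intercept) c(m$intercept, m$weights) else m$weights
  if (length(theta) != d) stop_protocol("summary dimension does not match model")
  reg <- regularizer(theta, control$fit_intercept)
  list(objective = sum(vapply(summaries, `[[`, 0, "objective_part")) + reg$objective,
       gradient = Reduce(`+`, lapply(summaries, `[[`, "gradient")) + reg$gradient,
       hessian = Reduce(`+`, lapply(summaries, `[[`, "hessian")) + reg$hessian,
       n_samples = sum(vapply(summaries, `[[`, 0, "n_samples")))
}

# Truncated conjugate gradient for H d = -g. Stops at relative residual
# `tol`, at `maxit` iterations, or on nonpositive curvature (returning the
# best direction so far; steepest descent if that happens immediately).
cg_solve <- function(H, g, tol, maxit) {
  d <- numeric(length(g))
  r <- -g
  p <- r
  rs <- sum(r * r)
  r0 <- sqrt(rs)
  if (r0 == 0) return(d)
  for (j in seq_len(maxit)) {
    Hp <- drop(H %*% p)
    pHp <- sum(p * Hp)
    if (pHp <= 0) {
      if (j == 1L) return(-g)
      return(d)
    }
    a <- rs / pHp
    d <- d + a * p
    r <- r - a * Hp
    rs_new <- sum(r * r)
    if (sqrt(rs_new) <= tol * r0) break
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  d
}

# Federated truncated-Newton loop. Coordinator-side: touches clients only
# through their closure interface and the aggregator; every objective
# evaluation of the Armijo line search is itself a federated aggregation.
newton_cg <- function(clients, control, aggregator) {
  n_clients <- length(clients)
  if (n_clients < 1L) stop_protocol("need at least one client")
  pooled_events <- sum(vapply(clients, function(cl) cl$n_events(), 0))
  if (pooled_events < 1L) {
    stop_invalid("no observed events across clients; ",
                 "the regression objective is degenerate on all-censored data")
  }

  fed_objective <- function(theta) {
    parts <- lapply(clients, function(cl) cl$objective_at(theta))
    aggregator$sum_tensors(parts) + regularizer(theta, control$fit_intercept)$objective
  }

  # Deterministic, scale-reasonable start: w = 0, b = mean of log-times
  # (itself a federated aggregate).
  moments <- aggregator$sum_tensors(lapply(clients, function(cl) cl$time_moments()))
  d <- clients[[1L]]$dim()
  theta <- numeric(d)
  if (control$fit_intercept) theta[1L] <- moments[2L] / moments[1L]

  rounds <- vector("list", control$max_iter)
  converged <- FALSE
  n_iter <- 0L
  f <- NA_real_
  c1 <- 1e-4

  for (r in seq_len(control$max_iter)) {
    summaries <- lapply(clients, function(cl) cl$summary_at(theta))
    obj_part <- aggregator$sum_tensors(lapply(summaries, `[[`, "objective_part"))
    grad_part <- aggregator$sum_tensors(lapply(summaries, `[[`, "gradient"))
    hess_part <- aggregator$sum_tensors(lapply(summaries, `[[`, "hessian"))
    reg <- regularizer(theta, control$fit_intercept)
    f <- obj_part + reg$objective
    g <- grad_part + reg$gradient
    H <- hess_part + reg$hessian
    gnorm <- max(abs(g))
    if (gnorm <= control$grad_tol) {
      converged <- TRUE
      break
    }

    dir <- cg_solve(H, g, control$cg_tol, maxit = d + 1L)
    slope <- sum(dir * g)
    fallback <- FALSE
    if (!is.finite(slope) || slope >= 0) {
      dir <- -g
      slope <- sum(dir * g)
      fallback <- TRUE
    }

    step <- 1
    ok <- FALSE
    for (ls in seq_len(30L)) {
      f_new <- fed_objective(theta + step * dir)
      if (f_new <= f + c1 * step * slope) {
        ok <- TRUE
        break
      }
      step <- step / 2
    }
    if (!ok) break  # line-search failure: stop, not converged

    theta <- theta + step * dir
    n_iter <- r
    rounds[[r]] <- data.frame(round_index = r, global_objective = f_new,
                              global_grad_norm = gnorm, step_size = step,
                              obj_evals = ls, steepest_fallback = fallback,
                              messages = aggregator$message_count())
  }

  rounds <- do.call(rbind, rounds[!vapply(rounds, is.null, TRUE)])
  list(theta = theta, converged = converged, n_iterations = n_iter,
       final_objective = fed_objective(theta),
       rounds = rounds %||% data.frame(), dim = d,
       messages = aggregator$message_count())
}

#' Fit a survival SVM across federated clients
#'
#' Runs the federated truncated-Newton loop: each round, every client
#' evaluates its local objective part, gradient, and Hessian at the broadcast
#' parameters; the coordinator sums them (plainly or via additive secret
#' sharing), adds the regularizer once, solves the Newton system by truncated
#' conjugate gradient, and backtracks along the direction with federated
#' objective evaluations until the Armijo condition holds. The result is
#' mathematically identical to the centralized fit on the pooled data, up to
#' float summation order (and fixed-point rounding when `use_smpc = TRUE`).
#'
#' @param datasets list of [survival_dataset()] objects, one per client, with
#'   identical feature schemas.
#' @param control an [svm_control()].
#' @param use_smpc mask all exchanged aggregates with additive secret sharing.
#' @param codec [fp_codec()] used when `use_smpc = TRUE`.
#' @param seed optional integer seeding the shard randomness (only consumed
#'   when `use_smpc = TRUE`); plain aggregation is fully deterministic.
#' @return an object of class `survsvm`; see [survsvm()].
#' @export
fit_federated <- function(datasets, control = svm_control(), use_smpc = FALSE,
                          codec = fp_codec(), seed = NULL) {
  if (!is.list(datasets) || length(datasets) < 1L) {
    stop_invalid("datasets must be a non-empty list of survival_dataset objects")
  }
  feature_names <- check_same_schema(datasets)
  if (use_smpc && !is.null(seed)) set.seed(seed)
  clients <- lapply(seq_along(datasets), function(k) {
    fs_client(datasets[[k]], control, client_id = paste0("client_", k))
  })
  agg <- make_aggregator(use_smpc, codec)
  res <- newton_cg(clients, control, agg)
  theta <- res$theta
  fit <- structure(
    list(coefficients = stats::setNames(
           if (control$fit_intercept) theta[-1L] else theta, feature_names),
         intercept = if (control$fit_intercept) theta[1L] else 0,
         converged = res$converged, n_iterations = res$n_iterations,
         final_objective = res$final_objective, control = control,
         n_clients = length(datasets),
         n_samples = vapply(datasets, function(d) length(d$times), 0),
         use_smpc = use_smpc, rounds = res$rounds, messages = res$messages,
         feature_names = feature_names, call = match.call()),
    class = "survsvm")
  fit
}

#' Fit a survival SVM on centralized (pooled) data
#'
#' The single-client degenerate case of [fit_federated()]: identical code
#' path, so the federated fit can be compared against it exactly.
#'
#' @param data a [survival_dataset()].
#' @param control an [svm_control()].
#' @return an object of class `survsvm`.
#' @export
fit_central <- function(data, control = svm_control()) {
  fit <- fit_federated(list(data), control = control, use_smpc = FALSE)
  fit$call <- match.call()
  fit
}
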