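# Independent oracles used across the suite. These deliberately re-derive
# quantities with plain loops / finite differences, separate from the
# package's vectorized implementations.

# Loss part of the objective (no regularizer), straight from the formula.
oracle_loss <- function(theta, X, logy, events, alpha, fit_intercept) {
  b <- if (fit_intercept) theta[1] else 0
  w <- if (fit_intercept) theta[-1] else theta
  total <- 0
  for (i in seq_along(logy)) {
    z <- logy[i] - sum(w * X[i, ]) - b
    if (events[i] == 0 && z < 0) z <- 0
    total <- total + z^2
  }
  0.5 * alpha * total
}

oracle_objective <- function(theta, X, logy, events, alpha, fit_intercept) {
  w <- if (fit_intercept) theta[-1] else theta
  0.5 * sum(w^2) + oracle_loss(theta, X, logy, events, alpha, fit_intercept)
}

# Central finite differences.
num_grad <- function(f, theta, h = 1e-6) {
  vapply(seq_along(theta), function(j) {
    tp <- theta; tm <- theta
    tp[j] <- tp[j] + h
    tm[j] <- tm[j] - h
    (f(tp) - f(tm)) / (2 * h)
  }, 0)
}

num_jacobian <- function(g, theta, h = 1e-6) {
  cols <- lapply(seq_along(theta), function(j) {
    tp <- theta; tm <- theta
    tp[j] <- tp[j] + h
    tm[j] <- tm[j] - h
    (g(tp) - g(tm)) / (2 * h)
  })
  do.call(cbind, cols)
}

# Brute-force Harrell c-index: enumerate every ordered pair.
brute_cindex <- function(times, events, risk) {
  conc <- disc <- tied <- 0
  n <- length(times)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      comparable <- (times[i] < times[j] && events[i] == 1) ||
        (times[i] == times[j] && events[i] == 1 && events[j] == 0)
      if (!comparable) next
      if (risk[i] > risk[j]) conc <- conc + 1
      else if (risk[i] < risk[j]) disc <- disc + 1
      else tied <- tied + 1
    }
  }
  if (conc + disc + tied == 0) return(NULL)
  list(concordant = conc, discordant = disc, tied_risk = tied,
       value = (conc + 0.5 * tied) / (conc + disc + tied))
}

# Small random problem instance for property tests.
rand_instance <- function(seed, n = 25, p = 4, censoring = 0.4) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  logy <- rnorm(n, 2, 1)
  events <- rbinom(n, 1, 1 - censoring)
  if (sum(events) == 0) events[1] <- 1
  list(X = X, logy = logy, events = events,
       data = survival_dataset(X, times = exp(logy), events = events))
}

rand_model <- function(seed, p) {
  set.seed(seed)
  list(weights = rnorm(p, 0, 0.5), intercept = rnorm(1, 2, 1))
}
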