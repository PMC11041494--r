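# Synthetic right-censored survival data with a known linear log-time
# signal. The generative family is log-normal: log T = w'x + b + eps,
# eps ~ N(0, noise_sd) — exactly the family for which the regression
# survival SVM is well-specified, so parameter recovery is a sharp test.
# Censoring times are independent draws whose location is calibrated by an
# empirical quantile of the realized true times, so the achieved censored
# fraction matches the target up to binomial noise.

#' Generate a synthetic right-censored survival dataset
#'
#' Features are standard normal; true log event times are
#' `w' x + b + N(0, noise_sd)`; independent log censoring times are drawn
#' with matching spread and shifted so the realized censored fraction is
#' close to `censoring`; observed time = min(event, censoring) in days.
#'
#' @param n number of samples.
#' @param p number of features.
#' @param true_weights length-p signal weights; default: `N(0,1)/sqrt(p)`
#'   draws (so the total signal variance is ~1 regardless of p).
#' @param intercept baseline log-time in log-days; the default 5
#'   corresponds to a median survival of ~150 days.
#' @param noise_sd standard deviation of the log-time noise.
#' @param censoring target censored fraction in `[0, 1)`.
#' @param seed integer seed; the dataset is fully reproducible from it.
#' @return a [survival_dataset()] with attribute `ground_truth`
#'   (list: `true_weights`, `intercept`, `noise_sd`, `realized_censoring`,
#'   `seed`).
#' @export
generate_survival <- function(n = 500, p = 10, true_weights = NULL,
                              intercept = 5, noise_sd = 0.3,
                              censoring = 0.3, seed = 1) {
  if (n < 1 || p < 1) stop_invalid("need n >= 1 and p >= 1")
  if (censoring < 0 || censoring >= 1) {
    stop_invalid("censoring target must be in [0, 1)")
  }
  set.seed(seed)
  w <- true_weights %||% (stats::rnorm(p) / sqrt(p))
  if (length(w) != p) stop_invalid("true_weights must have length p")
  X <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  log_t <- drop(X %*% w) + intercept + stats::rnorm(n, 0, noise_sd)

  if (censoring == 0) {
    log_obs <- log_t
    delta <- rep(1, n)
  } else {
    spread <- stats::sd(log_t)
    if (!is.finite(spread) || spread == 0) spread <- 1
    c0 <- stats::rnorm(n, 0, spread)
    # censored iff log_t > c0 + offset; picking offset as the (1 - q)
    # empirical quantile of log_t - c0 realizes a censored fraction ~ q.
    offset <- stats::quantile(log_t - c0, probs = 1 - censoring,
                              names = FALSE, type = 1)
    log_c <- c0 + offset
    delta <- as.numeric(log_t <= log_c)
    log_obs <- pmin(log_t, log_c)
  }
  ds <- survival_dataset(X, times = exp(log_obs), events = delta)
  attr(ds, "ground_truth") <- list(true_weights = w, intercept = intercept,
                                   noise_sd = noise_sd,
                                   realized_censoring = mean(1 - delta),
                                   seed = seed)
  ds
}

#' Partition a dataset across simulated clients
#'
#' Rows are shuffled and split into disjoint parts whose sizes follow
#' `fractions` with largest-remainder rounding, so the part sizes always sum
#' to n exactly (e.g. n = 100 with fractions 0.2/0.5/0.3 gives 20/50/30).
#'
#' @param data a [survival_dataset()].
#' @param fractions positive fractions summing to 1; one per client.
#' @param seed shuffle seed.
#' @return list of disjoint [survival_dataset()] parts.
#' @export
split_clients <- function(data, fractions = c(0.2, 0.5, 0.3), seed = 1) {
  if (any(fractions <= 0) || abs(sum(fractions) - 1) > 1e-9) {
    stop_invalid("fractions must be positive and sum to 1")
  }
  n <- length(data$times)
  if (n < length(fractions)) stop_invalid("fewer samples than clients")
  sizes <- floor(fractions * n)
  short <- n - sum(sizes)
  if (short > 0) {
    extra <- order(fractions * n - sizes, decreasing = TRUE)[seq_len(short)]
    sizes[extra] <- sizes[extra] + 1L
  }
  set.seed(seed)
  idx <- sample.int(n)
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  lapply(seq_along(sizes), function(k)
    dataset_subset(data, idx[starts[k]:ends[k]]))
}

#' Add a site-dependent batch effect
#'
#' Shifts every feature row of one site by a constant offset vector drawn
#' once per site from `N(0, batch_shift_sd)`; times and events are
#' untouched. Emulates systematic cross-institution differences in feature
#' distributions (assay, instrument, or population shifts).
#'
#' @param client_data the site's [survival_dataset()].
#' @param site_index 1-based site number; different sites get distinct
#'   offsets under the same seed.
#' @param batch_shift_sd standard deviation of the per-feature offset; 0 is
#'   the identity.
#' @param seed integer seed shared by all sites.
#' @return the shifted [survival_dataset()].
#' @export
apply_batch_effect <- function(client_data, site_index, batch_shift_sd,
                               seed = 1) {
  if (batch_shift_sd < 0) stop_invalid("batch_shift_sd must be >= 0")
  if (batch_shift_sd == 0) return(client_data)
  p <- ncol(client_data$features)
  set.seed(seed)
  # one offset vector per site, all reproducible from the shared seed
  offsets <- matrix(stats::rnorm(site_index * p, 0, batch_shift_sd),
                    nrow = site_index, byrow = TRUE)
  shift <- offsets[site_index, ]
  transform_features(client_data, function(X) sweep(X, 2, shift, "+"))
}

#' Shape presets mimicking published dataset scales
#'
#' `"highdim"` (n = 150, p = 1995) matches the shape of a shotgun
#' metagenomics cohort with ~2000 microbial species abundances;
#' `"large_n"` (n = 15564, p = 10) matches a large registry-style cohort.
#' Shape only — no claim of distributional fidelity.
#'
#' @param name preset name.
#' @return list with `n` and `p` for [generate_survival()].
#' @export
preset_shape <- function(name = c("highdim", "large_n")) {
  switch(match.arg(name),
         highdim = list(n = 150, p = 1995),
         large_n = list(n = 15564, p = 10))
}

#' @export
as.data.frame.survival_dataset <- function(x, ...) {
  data.frame(x$features, time = x$times, event = x$events)
}
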