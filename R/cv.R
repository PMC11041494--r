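# Repeated, event-stratified k-fold cross-validation of the federated
# workflow. Folds are assigned locally at each client with a shared seed, so
# all clients train on fold k simultaneously; stratification by event
# indicator protects small clients from all-censored folds. Normalization
# statistics are recomputed from the train folds only and applied to the
# held-out fold (no leakage), and every fold fits both the federated model
# and the pooled-data central model, so the report carries their weight
# divergence alongside the c-indices.

# Stratified fold assignment: shuffle within each event stratum, deal fold
# labels round-robin.
assign_folds <- function(events, n_folds, seed) {
  set.seed(seed)
  fold <- integer(length(events))
  for (e in unique(events)) {
    idx <- sample(which(events == e))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Cross-validate the federated survival SVM
#'
#' Runs `cv_repeats` x `cv_folds` cross-validation over the clients' training
#' data. Each fold fits the federated model and, as an oracle, the central
#' model on the pooled train folds, then reports per-site, mean-of-sites,
#' and pooled c-indices on the held-out folds plus the central-vs-federated
#' weight divergence.
#'
#' @param config a [workflow_config()] (or YAML path); its `cv_repeats`,
#'   `cv_folds`, `seed`, hyperparameters, and `use_smpc` flag drive the run.
#' @param datasets optional list of per-client [survival_dataset()] objects;
#'   when supplied, the CSV/encoding steps are skipped and `config` may be
#'   omitted.
#' @param ... with `datasets`, optional overrides: `cv_repeats`, `cv_folds`,
#'   `seed`, `alpha`, `fit_intercept`, `max_iter`, `use_smpc`, `normalize`.
#' @return list of class `fedsurv_cv`: `folds` (one row per rep x fold) and
#'   `summary` (aggregated over folds, with the site-mean-then-fold-mean and
#'   the all-folds pooled average both reported).
#' @export
cross_validate <- function(config = NULL, datasets = NULL, ...) {
  if (is.character(config)) config <- read_config(config)
  if (is.null(datasets)) {
    if (is.null(config)) stop_invalid("supply a config or datasets")
    prep <- prepare_clients_raw(config)
    datasets <- prep
  }
  opts <- list(...)
  getopt <- function(name, default) opts[[name]] %||% config[[name]] %||% default
  n_rep <- getopt("cv_repeats", 3L)
  n_folds <- getopt("cv_folds", 3L)
  if (n_folds < 2L) stop_invalid("cv_folds must be >= 2")
  seed <- getopt("seed", 1L)
  normalize <- getopt("normalize", TRUE)
  use_smpc <- getopt("use_smpc", FALSE)
  control <- svm_control(alpha = getopt("alpha", 1e-4),
                         fit_intercept = getopt("fit_intercept", TRUE),
                         max_iter = getopt("max_iter", 50L))

  rows <- list()
  for (r in seq_len(n_rep)) {
    folds <- lapply(datasets, function(d)
      assign_folds(d$events, n_folds, seed = seed + 7919L * r))
    for (k in seq_len(n_folds)) {
      tr <- mapply(function(d, f) dataset_subset(d, which(f != k)),
                   datasets, folds, SIMPLIFY = FALSE)
      te <- mapply(function(d, f) dataset_subset(d, which(f == k)),
                   datasets, folds, SIMPLIFY = FALSE)
      if (any(vapply(tr, function(d) length(d$times), 0) == 0) ||
          any(vapply(te, function(d) length(d$times), 0) == 0)) {
        warning(sprintf("repeat %d fold %d: a client has an empty fold; skipped",
                        r, k), call. = FALSE)
        next
      }
      if (normalize) {
        stats <- federated_normalization(tr, use_smpc = use_smpc)
        tr <- lapply(tr, apply_normalization, stats = stats)
        te <- lapply(te, apply_normalization, stats = stats)
      }
      fed <- fit_federated(tr, control = control, use_smpc = use_smpc,
                           seed = seed + 104729L * r + k)
      central <- fit_central(pool_datasets(tr), control = control)
      div <- weight_divergence(fed, central)

      site_ci <- lapply(te, function(d)
        tryCatch(harrell_cindex(d$times, d$events, predict(fed, d, type = "risk")),
                 fedsurv_undefined_result = function(e) NULL))
      defined <- !vapply(site_ci, is.null, TRUE)
      pooled_te <- pool_datasets(te)
      pooled_ci <- tryCatch(
        harrell_cindex(pooled_te$times, pooled_te$events,
                       predict(fed, pooled_te, type = "risk"))$value,
        fedsurv_undefined_result = function(e) NA_real_)
      central_ci <- tryCatch(
        harrell_cindex(pooled_te$times, pooled_te$events,
                       predict(central, pooled_te, type = "risk"))$value,
        fedsurv_undefined_result = function(e) NA_real_)

      rows[[length(rows) + 1L]] <- data.frame(
        repeat_index = r, fold = k,
        mean_site_cindex = if (any(defined))
          federated_cindex(site_ci[defined]) else NA_real_,
        pooled_cindex = pooled_ci, central_cindex = central_ci,
        max_weight_diff = div$max_abs_diff,
        mean_weight_diff = div$mean_abs_diff,
        converged = fed$converged)
    }
  }
  folds_df <- do.call(rbind, rows)
  if (is.null(folds_df) || nrow(folds_df) == 0L) {
    stop_invalid("no usable folds")
  }
  res <- list(
    folds = folds_df,
    summary = list(
      # site means averaged within fold, then across folds ...
      cindex_sitemean_foldmean = mean(folds_df$mean_site_cindex, na.rm = TRUE),
      # ... and the pooled view for comparison
      cindex_pooled_foldmean = mean(folds_df$pooled_cindex, na.rm = TRUE),
      cindex_central_foldmean = mean(folds_df$central_cindex, na.rm = TRUE),
      max_weight_diff = max(folds_df$max_weight_diff),
      mean_weight_diff = mean(folds_df$mean_weight_diff),
      n_folds_run = nrow(folds_df)))
  class(res) <- "fedsurv_cv"
  res
}

#' @export
print.fedsurv_cv <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Federated survival-SVM CV over %d folds\n", s$n_folds_run))
  cat(sprintf("  c-index  mean-of-sites: %.4f   pooled: %.4f   central: %.4f\n",
              s$cindex_sitemean_foldmean, s$cindex_pooled_foldmean,
              s$cindex_central_foldmean))
  cat(sprintf("  weight divergence vs central  max: %.3g   mean: %.3g\n",
              s$max_weight_diff, s$mean_weight_diff))
  invisible(x)
}

# Concatenate client datasets (pooled oracle).
pool_datasets <- function(datasets) {
  check_same_schema(datasets)
  survival_dataset(do.call(rbind, lapply(datasets, `[[`, "features")),
                   times = unlist(lapply(datasets, `[[`, "times")),
                   events = unlist(lapply(datasets, `[[`, "events")),
                   feature_names = datasets[[1L]]$feature_names,
                   sample_ids = unlist(lapply(datasets, `[[`, "sample_ids")))
}

# Config path of cross_validate: read + encode the train CSVs (no
# normalization here; it happens per fold).
prepare_clients_raw <- function(config) {
  tc <- config$time_column; ec <- config$event_column; ic <- config$id_column
  tabs <- lapply(config$clients, function(cl)
    read_survival_table(cl$train_csv, tc, ec, ic))
  enc <- onehot_encoder(tabs, config$categorical_columns)
  tabs <- lapply(tabs, apply_onehot, encoder = enc)
  lapply(tabs, table_to_dataset, time_column = tc, event_column = ec,
         id_column = ic)
}
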