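# End-to-end workflow over per-client CSV files: ingestion and validation,
# federated one-hot encoding and normalization, federated SVM fit, and
# per-client prediction/evaluation outputs. Mirrors how a multi-site
# deployment is driven by a shared config file: every client supplies one
# training and one test CSV with identical column schemas.

#' Workflow configuration
#'
#' @param clients list of `list(train_csv=, test_csv=)` paths, one per client.
#' @param time_column,event_column names of the survival-time (positive,
#'   days) and event-indicator columns.
#' @param id_column optional sample-id column; row numbers otherwise.
#' @param categorical_columns columns to one-hot encode with a federated
#'   level union.
#' @param normalize apply federated z-score normalization (train-fold
#'   statistics only, applied to test data).
#' @param alpha,fit_intercept,max_iter hyperparameters, see [svm_control()].
#' @param use_smpc mask all exchanged aggregates with additive secret
#'   sharing.
#' @param cv_repeats,cv_folds repeated k-fold CV layout for
#'   [cross_validate()].
#' @param seed integer seed driving fold assignment and shard randomness.
#' @param output_dir where [run_workflow()] writes its outputs.
#' @return validated config list, class `fedsurv_config`.
#' @export
workflow_config <- function(clients, time_column = "time",
                            event_column = "event", id_column = NULL,
                            categorical_columns = character(),
                            normalize = TRUE, alpha = 1e-4,
                            fit_intercept = TRUE, max_iter = 50L,
                            use_smpc = FALSE, cv_repeats = 3L, cv_folds = 3L,
                            seed = 1L, output_dir = NULL) {
  if (length(clients) < 1L) stop_invalid("need at least one client")
  for (cl in clients) {
    if (is.null(cl$train_csv)) stop_invalid("every client needs a train_csv")
  }
  structure(list(clients = clients, time_column = time_column,
                 event_column = event_column, id_column = id_column,
                 categorical_columns = as.character(categorical_columns),
                 normalize = isTRUE(normalize), alpha = alpha,
                 fit_intercept = isTRUE(fit_intercept),
                 max_iter = as.integer(max_iter),
                 use_smpc = isTRUE(use_smpc),
                 cv_repeats = as.integer(cv_repeats),
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed),
                 output_dir = output_dir),
            class = "fedsurv_config")
}

#' Read a workflow config from YAML
#' @param path YAML file with the fields of [workflow_config()].
#' @return validated config list.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(workflow_config, raw)
}

parse_events <- function(v, path = "<data>") {
  if (is.logical(v)) return(as.numeric(v))
  if (is.numeric(v)) {
    if (!all(v %in% c(0, 1))) {
      stop_invalid(path, ": event column must be binary 0/1")
    }
    return(as.numeric(v))
  }
  lv <- tolower(trimws(as.character(v)))
  out <- rep(NA_real_, length(lv))
  out[lv %in% c("1", "true")] <- 1
  out[lv %in% c("0", "false")] <- 0
  if (anyNA(out)) {
    stop_invalid(path, ": unparseable event values: ",
                 paste(utils::head(unique(v[is.na(out)]), 3L), collapse = ", "))
  }
  out
}

#' Read and validate one client's survival CSV
#'
#' Comma-separated, UTF-8, header row required. Events are parsed from
#' 0/1/true/false (any case); times must be strictly positive numbers.
#'
#' @param path CSV file path.
#' @param time_column,event_column,id_column column names (id optional).
#' @return a validated data.frame with numeric `time_column` and 0/1
#'   `event_column`; row order preserved.
#' @export
read_survival_table <- function(path, time_column = "time",
                                event_column = "event", id_column = NULL) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  for (col in c(time_column, event_column, id_column)) {
    if (!col %in% names(tab)) {
      stop_invalid(path, ": missing required column '", col, "'")
    }
  }
  tms <- suppressWarnings(as.numeric(tab[[time_column]]))
  bad <- which(!is.finite(tms) | tms <= 0)
  if (length(bad) > 0L) {
    stop_invalid(path, ": nonpositive or missing survival time in row(s) ",
                 paste(utils::head(bad, 5L), collapse = ", "),
                 " (survival times must be > 0)")
  }
  tab[[time_column]] <- tms
  tab[[event_column]] <- parse_events(tab[[event_column]], path)
  tab
}

# Validated table -> survival_dataset; feature columns are everything except
# time/event/id.
table_to_dataset <- function(tab, time_column, event_column,
                             id_column = NULL) {
  drop <- c(time_column, event_column, id_column)
  feats <- tab[, setdiff(names(tab), drop), drop = FALSE]
  ids <- if (!is.null(id_column)) as.character(tab[[id_column]]) else
    as.character(seq_len(nrow(tab)))
  survival_dataset(feats, times = tab[[time_column]],
                   events = tab[[event_column]], sample_ids = ids)
}

#' Read one client's CSV straight into a dataset
#'
#' Convenience wrapper: [read_survival_table()] followed by dataset
#' construction; every non-time/event/id column becomes a numeric feature.
#' Categorical columns must be one-hot encoded first (see
#' [onehot_encoder()]), which [run_workflow()] does across clients.
#'
#' @inheritParams read_survival_table
#' @return a [survival_dataset()].
#' @export
read_survival_csv <- function(path, time_column = "time",
                              event_column = "event", id_column = NULL) {
  tab <- read_survival_table(path, time_column, event_column, id_column)
  table_to_dataset(tab, time_column, event_column, id_column)
}

#' Serialize / load a fitted model as portable JSON
#'
#' @param fit a `survsvm` object.
#' @param path output file.
#' @param normalization optional [global_normalization()] stats to embed.
#' @param encoder optional [onehot_encoder()] to embed.
#' @export
write_model_json <- function(fit, path, normalization = NULL,
                             encoder = NULL) {
  doc <- list(model = "survival_svm_regression",
              feature_names = fit$feature_names,
              weights = unname(fit$coefficients), intercept = fit$intercept,
              alpha = fit$control$alpha, rank_ratio = 0,
              fit_intercept = fit$control$fit_intercept,
              converged = fit$converged, n_iterations = fit$n_iterations,
              final_objective = fit$final_objective,
              use_smpc = fit$use_smpc,
              normalization = if (!is.null(normalization))
                normalization[c("mean", "std")],
              onehot_levels = if (!is.null(encoder)) encoder$levels)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(coefficients = stats::setNames(doc$weights,
                                                doc$feature_names),
                 intercept = doc$intercept,
                 control = svm_control(alpha = doc$alpha,
                                       fit_intercept = doc$fit_intercept),
                 converged = doc$converged, n_iterations = doc$n_iterations,
                 final_objective = doc$final_objective,
                 use_smpc = doc$use_smpc, n_clients = NA_integer_,
                 n_samples = NA_integer_,
                 feature_names = doc$feature_names,
                 normalization = doc$normalization,
                 onehot_levels = doc$onehot_levels),
            class = "survsvm")
}

# Shared preprocessing front end: read all client tables, check schemas,
# one-hot encode with the federated level union, normalize with federated
# train-fold moments. Returns train/test datasets plus the fitted
# preprocessing state.
prepare_clients <- function(config) {
  tc <- config$time_column; ec <- config$event_column; ic <- config$id_column
  train_tabs <- lapply(config$clients, function(cl)
    read_survival_table(cl$train_csv, tc, ec, ic))
  test_tabs <- lapply(config$clients, function(cl) {
    if (is.null(cl$test_csv)) NULL else read_survival_table(cl$test_csv, tc, ec, ic)
  })
  schema <- names(train_tabs[[1L]])
  for (k in seq_along(train_tabs)) {
    if (!identical(sort(names(train_tabs[[k]])), sort(schema))) {
      stop_protocol("client ", k, " train CSV schema differs from client 1")
    }
  }
  enc <- onehot_encoder(train_tabs, config$categorical_columns)
  train_tabs <- lapply(train_tabs, apply_onehot, encoder = enc)
  test_tabs <- lapply(test_tabs, function(tb)
    if (is.null(tb)) NULL else apply_onehot(enc, tb))
  train <- lapply(train_tabs, table_to_dataset, time_column = tc,
                  event_column = ec, id_column = ic)
  test <- lapply(test_tabs, function(tb)
    if (is.null(tb)) NULL else table_to_dataset(tb, tc, ec, ic))
  check_same_schema(train)
  stats <- NULL
  if (config$normalize) {
    stats <- federated_normalization(train, use_smpc = config$use_smpc)
    train <- lapply(train, apply_normalization, stats = stats)
    test <- lapply(test, function(d)
      if (is.null(d)) NULL else apply_normalization(d, stats))
  }
  list(train = train, test = test, encoder = enc, normalization = stats)
}

#' Federated normalization statistics from client datasets
#'
#' Aggregates [local_moments()] across clients — through [secure_sum()] when
#' `use_smpc` — and combines them with [global_normalization()]; the result
#' equals the pooled-data statistics exactly.
#'
#' @param datasets list of [survival_dataset()] objects.
#' @param use_smpc exchange the moment vectors as secret shares.
#' @param codec [fp_codec()] for the secure exchange.
#' @export
federated_normalization <- function(datasets, use_smpc = FALSE,
                                    codec = fp_codec()) {
  moms <- lapply(datasets, local_moments)
  if (use_smpc) {
    packed <- lapply(moms, function(m) c(m$n, m$sum, m$sum_sq))
    tot <- secure_sum(packed, codec)
    p <- length(moms[[1L]]$sum)
    nm <- names(moms[[1L]]$sum)
    moms <- list(list(n = tot[1L], sum = stats::setNames(tot[2:(p + 1L)], nm),
                      sum_sq = stats::setNames(tot[(p + 2L):(2L * p + 1L)], nm)))
  }
  global_normalization(moms)
}

#' Run the full federated workflow
#'
#' Reads every client's train/test CSVs, one-hot encodes with a federated
#' category union, normalizes with federated train statistics, fits the
#' federated survival SVM, and writes per-client outputs: the global model
#' (JSON) and a predictions CSV (`sample_id, predicted_log_time,
#' predicted_risk`), plus an evaluation report, a per-round optimization
#' log, and an echo of the resolved configuration.
#'
#' @param config a [workflow_config()] (or path to its YAML file).
#' @return invisibly, a list with the fit, the evaluation report, and the
#'   output directory.
#' @export
run_workflow <- function(config) {
  if (is.character(config)) config <- read_config(config)
  prep <- prepare_clients(config)
  control <- svm_control(alpha = config$alpha,
                         fit_intercept = config$fit_intercept,
                         max_iter = config$max_iter)
  fit <- fit_federated(prep$train, control = control,
                       use_smpc = config$use_smpc, seed = config$seed)

  out <- config$output_dir %||% tempfile("fedsurv_run_")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  site_cindex <- vector("list", length(prep$test))
  for (k in seq_along(prep$test)) {
    cdir <- file.path(out, sprintf("client_%d", k))
    dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
    write_model_json(fit, file.path(cdir, "model.json"),
                     normalization = prep$normalization,
                     encoder = prep$encoder)
    ds <- prep$test[[k]]
    if (is.null(ds)) next
    lp <- predict(fit, ds)
    utils::write.csv(data.frame(sample_id = ds$sample_ids,
                                predicted_log_time = lp,
                                predicted_risk = -lp),
                     file.path(cdir, "predictions.csv"), row.names = FALSE)
    site_cindex[[k]] <- tryCatch(
      harrell_cindex(ds$times, ds$events, -lp),
      fedsurv_undefined_result = function(e) NULL)
  }

  have_test <- !vapply(prep$test, is.null, TRUE)
  report <- list(
    n_clients = length(prep$train),
    n_train = vapply(prep$train, function(d) length(d$times), 0),
    use_smpc = config$use_smpc, converged = fit$converged,
    n_iterations = fit$n_iterations,
    site_cindex = lapply(site_cindex, function(r)
      if (is.null(r)) NULL else r$value),
    federated_cindex = if (any(have_test) &&
                           !all(vapply(site_cindex, is.null, TRUE)))
      federated_cindex(site_cindex[have_test]) else NULL,
    pooled_cindex = if (any(have_test)) {
      pooled <- Reduce(function(a, b) {
        list(times = c(a$times, b$times), events = c(a$events, b$events),
             risk = c(a$risk, b$risk))
      }, lapply(which(have_test), function(k) {
        ds <- prep$test[[k]]
        list(times = ds$times, events = ds$events,
             risk = -predict(fit, ds))
      }))
      tryCatch(harrell_cindex(pooled$times, pooled$events, pooled$risk)$value,
               fedsurv_undefined_result = function(e) NULL)
    } else NULL)
  jsonlite::write_json(report, file.path(out, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  if (!is.null(fit$rounds) && nrow(fit$rounds) > 0L) {
    con <- file(file.path(out, "round_log.ndjson"), "w")
    for (i in seq_len(nrow(fit$rounds))) {
      writeLines(jsonlite::toJSON(as.list(fit$rounds[i, ]),
                                  auto_unbox = TRUE, digits = NA), con)
    }
    close(con)
  }
  echo <- unclass(config)
  echo$categorical_columns <- as.list(echo$categorical_columns)
  yaml::write_yaml(echo, file.path(out, "config_echo.yaml"))
  invisible(list(fit = fit, report = report, output_dir = out,
                 normalization = prep$normalization, encoder = prep$encoder))
}
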