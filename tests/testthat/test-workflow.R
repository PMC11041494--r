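# Helpers building small per-client CSV scenarios in a temp dir.
write_client_csvs <- function(dir, n = 120, p = 3, clients = c(0.5, 0.5),
                              seed = 71, test_n = 20) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- generate_survival(n = n, p = p, seed = seed)
  parts <- split_clients(d, clients, seed = seed)
  cfg_clients <- list()
  for (k in seq_along(parts)) {
    pd <- parts[[k]]
    te <- seq_len(test_n)
    tr_path <- file.path(dir, sprintf("c%d_train.csv", k))
    te_path <- file.path(dir, sprintf("c%d_test.csv", k))
    utils::write.csv(as.data.frame(fedsurv:::dataset_subset(
      pd, setdiff(seq_along(pd$times), te))), tr_path, row.names = FALSE)
    utils::write.csv(as.data.frame(fedsurv:::dataset_subset(pd, te)),
                     te_path, row.names = FALSE)
    cfg_clients[[k]] <- list(train_csv = tr_path, test_csv = te_path)
  }
  cfg_clients
}

test_that("CSV ingestion validates columns, events, and times", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("time,event,x1,x2", "10,1,0.5,1.2", "20,0,-0.3,0.8",
               "5,1,0.0,0.1"), f)
  d <- read_survival_csv(f)
  expect_equal(dim(d), c(3L, 2L))
  expect_equal(d$times, c(10, 20, 5))

  f2 <- tempfile(fileext = ".csv")
  writeLines(c("time,event,x1", "3,True,1", "4,False,2"), f2)
  d2 <- read_survival_csv(f2)
  expect_equal(d2$events, c(1, 0))

  f3 <- tempfile(fileext = ".csv")
  writeLines(c("time,event,x1", "0,1,1", "4,0,2"), f3)
  expect_error(read_survival_csv(f3), "row")
  expect_error(read_survival_csv(f, time_column = "followup"),
               "followup", class = "fedsurv_invalid_input")
  expect_error(read_survival_table(tempfile(), "time", "event"),
               class = "fedsurv_invalid_input")
})

test_that("single-client workflow equals the direct central pipeline", {
  dir <- tempfile("wf1_")
  cfg <- workflow_config(write_client_csvs(dir, clients = 1.0),
                         normalize = TRUE, seed = 5,
                         output_dir = file.path(dir, "out"))
  res <- run_workflow(cfg)

  # direct pipeline on the same CSVs
  tr <- read_survival_csv(cfg$clients[[1]]$train_csv)
  te <- read_survival_csv(cfg$clients[[1]]$test_csv)
  gn <- global_normalization(list(local_moments(tr)))
  fit <- fit_central(apply_normalization(tr, gn))
  expect_equal(unname(coef(res$fit)), unname(coef(fit)), tolerance = 1e-12)
  preds <- utils::read.csv(file.path(res$output_dir, "client_1",
                                     "predictions.csv"))
  expect_equal(preds$predicted_log_time,
               predict(fit, apply_normalization(te, gn)), tolerance = 1e-10)
  expect_equal(preds$predicted_risk, -preds$predicted_log_time)

  # persisted model reloads losslessly
  m <- read_model_json(file.path(res$output_dir, "client_1", "model.json"))
  expect_equal(unname(m$coefficients), unname(coef(res$fit)[-1]))
  expect_equal(m$intercept, res$fit$intercept)
  expect_equal(unlist(m$normalization$mean), unname(gn$mean))
})

test_that("SMPC toggle leaves workflow predictions unchanged within 1e-6", {
  dir <- tempfile("wf2_")
  clients <- write_client_csvs(dir, n = 150, clients = c(0.4, 0.3, 0.3))
  out_a <- file.path(dir, "a"); out_b <- file.path(dir, "b")
  ra <- run_workflow(workflow_config(clients, use_smpc = FALSE, seed = 11,
                                     output_dir = out_a))
  rb <- run_workflow(workflow_config(clients, use_smpc = TRUE, seed = 11,
                                     output_dir = out_b))
  for (k in 1:3) {
    pa <- utils::read.csv(file.path(out_a, sprintf("client_%d", k),
                                    "predictions.csv"))
    pb <- utils::read.csv(file.path(out_b, sprintf("client_%d", k),
                                    "predictions.csv"))
    expect_lt(max(abs(pa$predicted_log_time - pb$predicted_log_time)), 1e-6)
  }
  expect_true(file.exists(file.path(out_a, "evaluation.json")))
  expect_true(file.exists(file.path(out_a, "round_log.ndjson")))
})

test_that("the echoed config reproduces the run byte for byte", {
  dir <- tempfile("wf3_")
  cfg <- workflow_config(write_client_csvs(dir), seed = 3,
                         output_dir = file.path(dir, "out1"))
  r1 <- run_workflow(cfg)
  echo <- read_config(file.path(r1$output_dir, "config_echo.yaml"))
  echo$output_dir <- file.path(dir, "out2")
  r2 <- run_workflow(echo)
  p1 <- readLines(file.path(r1$output_dir, "client_1", "predictions.csv"))
  p2 <- readLines(file.path(r2$output_dir, "client_1", "predictions.csv"))
  expect_identical(p1, p2)
})

test_that("workflow runs one-hot encoding across clients", {
  dir <- tempfile("wf4_")
  dir.create(dir)
  set.seed(9)
  mk <- function(path, stages, n) {
    d <- generate_survival(n = n, p = 2, seed = sample.int(1000, 1))
    df <- as.data.frame(d)
    df$stage <- sample(stages, n, replace = TRUE)
    utils::write.csv(df, path, row.names = FALSE)
    path
  }
  c1 <- list(train_csv = mk(file.path(dir, "t1.csv"), c("I", "II"), 60),
             test_csv = mk(file.path(dir, "e1.csv"), c("I", "II"), 20))
  c2 <- list(train_csv = mk(file.path(dir, "t2.csv"), c("II", "III"), 60),
             test_csv = mk(file.path(dir, "e2.csv"), c("II", "III"), 20))
  res <- run_workflow(workflow_config(list(c1, c2),
                                      categorical_columns = "stage",
                                      output_dir = file.path(dir, "out")))
  expect_setequal(res$encoder$levels$stage, c("I", "II", "III"))
  expect_true(all(c("stage.I", "stage.II", "stage.III") %in%
                  res$fit$feature_names))
})

test_that("schema disagreement across clients fails before fitting", {
  dir <- tempfile("wf5_")
  dir.create(dir)
  d1 <- as.data.frame(generate_survival(n = 30, p = 2, seed = 1))
  d2 <- as.data.frame(generate_survival(n = 30, p = 3, seed = 2))
  f1 <- file.path(dir, "a.csv"); f2 <- file.path(dir, "b.csv")
  utils::write.csv(d1, f1, row.names = FALSE)
  utils::write.csv(d2, f2, row.names = FALSE)
  expect_error(
    run_workflow(workflow_config(list(list(train_csv = f1),
                                      list(train_csv = f2)))),
    class = "fedsurv_protocol_error")
})

test_that("cross-validation produces the full repeats-by-folds grid", {
  d <- generate_survival(n = 180, p = 4, seed = 81)
  parts <- split_clients(d, c(0.2, 0.5, 0.3), seed = 82)
  cv <- cross_validate(datasets = parts, cv_repeats = 3, cv_folds = 3,
                       seed = 7, alpha = 1e-4)
  expect_equal(nrow(cv$folds), 9L)
  expect_true(all(cv$folds$converged))
  # central-vs-federated divergence bound holds in every fold
  expect_lte(max(cv$folds$max_weight_diff), 0.001)
  expect_true(all(is.finite(cv$folds$mean_site_cindex)))
  expect_true(all(c("cindex_sitemean_foldmean", "cindex_pooled_foldmean") %in%
                  names(cv$summary)))
})

test_that("fold assignment is stratified, disjoint, and exhaustive", {
  set.seed(1)
  events <- rbinom(90, 1, 0.3)
  f <- fedsurv:::assign_folds(events, 3, seed = 4)
  expect_setequal(unique(f), 1:3)
  expect_length(f, 90)
  # every fold sees both strata in close-to-equal proportion
  for (k in 1:3) {
    expect_gt(sum(events[f == k]), 0)
    expect_gt(sum(1 - events[f == k]), 0)
  }
  counts <- table(f, events)
  expect_lte(max(counts[, "1"]) - min(counts[, "1"]), 1)
})
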