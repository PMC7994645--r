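test_that("cell-line partition is stratified, disjoint and deterministic", {
  set.seed(2)
  lines <- sprintf("cl%02d", 1:20)
  aac <- matrix(runif(5 * 20), 5, 20,
                dimnames = list(paste0("d", 1:5), lines))
  resp <- drug_response_table(aac, scaled = TRUE)
  part <- partition_cell_lines(lines, resp, ratio = 0.8, seed = 9L)
  expect_length(part$train, 16L)
  expect_length(part$validation, 4L)
  expect_setequal(c(part$train, part$validation), lines)
  expect_length(intersect(part$train, part$validation), 0L)
  expect_identical(partition_cell_lines(lines, resp, seed = 9L), part)
  expect_error(partition_cell_lines(lines[1:5], resp), "at least 10")
})

test_that("noiseless linear targets are recovered exactly by pls", {
  set.seed(30)
  X <- matrix(runif(20 * 5), 20, 5,
              dimnames = list(paste0("c", 1:20), paste0("p", 1:5)))
  y <- 0.2 + 0.6 * X[, 1]
  models <- train_drug_models(X, y, roster = "pls", seed = 42L)
  expect_identical(models$pls$status, "ok")
  expect_lt(models$pls$cv_rmse, 1e-6)
  # LOOCV protocol: one resample per training line
  expect_length(models$pls$cv_resample_rmse, 20L)
})

test_that("pure-noise targets show no spurious cross-validated skill", {
  set.seed(55)
  ratios <- replicate(20, {
    X <- matrix(runif(20 * 5), 20, 5,
                dimnames = list(paste0("c", 1:20), paste0("p", 1:5)))
    y <- rnorm(20, 0.5, 0.15)
    m <- train_drug_models(X, y, roster = "pcr", seed = 1L)
    m$pcr$cv_rmse / sd(y)
  })
  expect_lt(abs(mean(ratios) - 1), 0.25)
})

test_that("every roster algorithm trains, predicts in range, and records CV", {
  set.seed(60)
  X <- matrix(runif(20 * 6), 20, 6,
              dimnames = list(paste0("c", 1:20), paste0("p", 1:6)))
  y <- pmin(pmax(0.5 * X[, 1] + 0.3 * X[, 2] + rnorm(20, 0, 0.05), 0), 1)
  models <- train_drug_models(X, y, cv_repeats = 1L, seed = 7L)
  expect_setequal(names(models), names(algorithm_registry()))
  for (a in names(models)) {
    expect_identical(models[[a]]$status, "ok")
    expect_true(is.finite(models[[a]]$cv_rmse))
  }
  # repeated-CV resample count: k folds x repeats (here 10 x 1)
  expect_length(models$random_forest$cv_resample_rmse, 10L)
  # pls/pcr use LOOCV regardless of the repeated-CV spec
  expect_length(models$pcr$cv_resample_rmse, 20L)
})

test_that("ensemble predictions respect the AAC scale and in-sample optimism", {
  pipe <- ref_pipeline()
  ens <- pipe$ensemble
  # rf CV record holds 30 resamples (10-fold x 3 repeats)
  d <- names(ens$drugs)[[1]]
  expect_length(ens$drugs[[d]]$models$random_forest$cv_resample_rmse, 30L)

  # predicting the training panel: training RMSE <= CV RMSE per drug
  dm_train <- pipe$distances
  keep <- pipe$partition$train
  for (nm in c("D", "S_Q2", "S_Q3", "R_Q2", "R_Q3",
               "coverage_sensitivity", "coverage_resistance"))
    dm_train[[nm]] <- dm_train[[nm]][, keep, drop = FALSE]
  pred_tr <- predict_responses(ens, dm_train, algorithm = "random_forest")
  expect_true(all(pred_tr >= 0 & pred_tr <= 1, na.rm = TRUE))
  worse <- 0L; total <- 0L
  for (d in rownames(pred_tr)) {
    ent <- ens$drugs[[d]]
    if (!identical(ent$status, "ok")) next
    obs <- pipe$responses$aac[d, ent$train_lines]
    fitv <- pred_tr[d, ent$train_lines]
    ok <- !is.na(fitv)
    if (sum(ok) < 5) next
    total <- total + 1L
    if (sqrt(mean((obs[ok] - fitv[ok])^2)) >
        ent$models$random_forest$cv_rmse) worse <- worse + 1L
  }
  expect_gt(total, 10L)
  expect_equal(worse, 0L)

  expect_error(predict_responses(ens, dm_train, algorithm = "nope"),
               "unknown algorithm")
})

test_that("consensus is the mean of available member predictions", {
  pipe <- ref_pipeline()
  panel <- ref_panel()
  # train a small 3-member ensemble on the reference artifacts
  ens3 <- train_ensemble(pipe$distances_norm, pipe$responses,
                         pipe$predictor_sets[1:3], pipe$partition$train,
                         roster = c("random_forest", "pcr", "pls"),
                         cv_repeats = 1L, seed = 5L)
  dm_val <- pipe$distances
  for (nm in c("D", "S_Q2", "S_Q3", "R_Q2", "R_Q3",
               "coverage_sensitivity", "coverage_resistance"))
    dm_val[[nm]] <- dm_val[[nm]][, pipe$partition$validation, drop = FALSE]
  p_rf <- predict_responses(ens3, dm_val, "random_forest")
  p_pcr <- predict_responses(ens3, dm_val, "pcr")
  p_pls <- predict_responses(ens3, dm_val, "pls")
  p_cons <- predict_responses(ens3, dm_val, "consensus")
  manual <- pmin(pmax((p_rf + p_pcr + p_pls) / 3, 0), 1)
  ok <- !is.na(p_cons)
  expect_equal(unclass(p_cons)[ok], unclass(manual)[ok], tolerance = 1e-12)

  # dropping one member leaves the mean of the remaining two
  ens2 <- ens3
  d <- names(ens2$drugs)[[1]]
  ens2$drugs[[d]]$models$pls$status <- "unavailable: forced"
  p2 <- predict_responses(ens2, dm_val, "consensus")
  manual2 <- pmin(pmax((p_rf[d, ] + p_pcr[d, ]) / 2, 0), 1)
  expect_equal(unclass(p2)[d, ], unname(manual2), tolerance = 1e-12,
               ignore_attr = TRUE)

  # a lone member yields no consensus
  ens1 <- ens2
  ens1$drugs[[d]]$models$pcr$status <- "unavailable: forced"
  p1 <- predict_responses(ens1, dm_val, "consensus")
  expect_true(all(is.na(p1[d, ])))
})

test_that("mean-prediction stratification splits high from low", {
  p <- c(a = 0.2, b = 0.4, c = 0.9)
  expect_equal(stratify_by_mean_prediction(p),
               c(a = "low", b = "low", c = "high"))
  expect_true(all(stratify_by_mean_prediction(c(x = 0.5, y = 0.5)) == "low"))
  shifted <- stratify_by_mean_prediction(p + 0.07)
  expect_equal(unname(shifted), unname(stratify_by_mean_prediction(p)))
})

test_that("the two-hidden-layer perceptron gradient matches finite differences", {
  set.seed(12)
  X <- matrix(rnorm(30), 10, 3)
  y <- rnorm(10)
  obj <- emdrank:::mlp2_objective(X, y, h1 = 4L, h2 = 3L, decay = 0.05)
  w <- rnorm(obj$n_par, sd = 0.3)
  num_grad <- vapply(seq_len(obj$n_par), function(j) {
    h <- 1e-6; e <- numeric(obj$n_par); e[j] <- h
    (obj$loss(w + e) - obj$loss(w - e)) / (2 * h)
  }, numeric(1))
  expect_equal(obj$grad(w), num_grad, tolerance = 1e-6)

  set.seed(13)
  fit <- emdrank:::fit_mlp2(X, y, sizes = c(4L, 3L), decay = 0.05,
                            maxit = 100L)
  expect_s3_class(fit, "emdrank_mlp2")
  # training reduces the objective below the constant-mean baseline
  pred <- emdrank:::predict_mlp2(fit, X)
  expect_lt(mean((pred - y)^2), mean((mean(y) - y)^2))
})

test_that("the leakage guard rejects contaminated stage inputs", {
  expect_silent(assert_no_leakage(c("v1", "v2"),
                                  list(discovery = c("t1", "t2"))))
  expect_error(assert_no_leakage(c("v1"), list(discovery = c("t1", "v1"))),
               "leakage.*discovery")
})
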