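test_that("median split sends ties to the sensitive group", {
  x <- c(a = 0.1, b = 0.2, c = 0.8, d = 0.9)
  sp <- split_sensitive_resistant(x, min_group_size = 2L)
  expect_setequal(sp$sensitive, c("c", "d"))
  expect_setequal(sp$resistant, c("a", "b"))

  # exact median ties land in the sensitive group
  z <- c(a = 0.1, b = 0.5, c = 0.9, d = 0.5, e = 0.2)
  sp3 <- split_sensitive_resistant(z, min_group_size = 2L)
  expect_setequal(sp3$sensitive, c("b", "c", "d"))
  expect_setequal(sp3$resistant, c("a", "e"))

  expect_error(split_sensitive_resistant(rep(0.5, 12)), "degenerate")
  expect_error(split_sensitive_resistant(c(a = 1, b = 0)), "too few")
})

test_that("resample groups are leave-one-fold-out subsets", {
  members <- sprintf("cl%02d", 1:10)
  gr <- make_resample_groups(members, k = 10L, seed = 3L)
  expect_length(gr, 10L)
  expect_true(all(lengths(gr) == 9L))
  # each subset plus its excluded fold reconstitutes the member set
  for (g in gr) expect_setequal(union(g, setdiff(members, g)), members)
  # excluded folds partition the members
  excluded <- lapply(gr, function(g) setdiff(members, g))
  expect_setequal(unlist(excluded), members)
  # determinism
  expect_identical(make_resample_groups(members, k = 10L, seed = 3L), gr)
  expect_error(make_resample_groups("one"), "at least 2")
})

test_that("pair screening retains separable pairs and matches Welch oracle", {
  aac <- c(setNames(rep(0.9, 10), paste0("s", 1:10)),
           setNames(rep(0.1, 10), paste0("r", 1:10)))
  sg <- make_resample_groups(paste0("s", 1:10), seed = 1)
  rg <- make_resample_groups(paste0("r", 1:10), seed = 2)
  ret <- screen_group_pairs(sg, rg, aac)
  expect_equal(nrow(ret), 100L)  # maximal separation: every pair retained

  flat <- setNames(rep(0.5, 20), names(aac))
  expect_equal(nrow(screen_group_pairs(sg, rg, flat)), 0L)

  # overlapping case agrees with an independent Welch re-test of every pair
  set.seed(11)
  noisy <- c(setNames(rnorm(10, 0.6, 0.2), paste0("s", 1:10)),
             setNames(rnorm(10, 0.45, 0.2), paste0("r", 1:10)))
  ret2 <- screen_group_pairs(sg, rg, noisy)
  manual <- 0L
  for (i in 1:10) for (j in 1:10) {
    if (oracle_welch_p(noisy[sg[[i]]], noisy[rg[[j]]]) < 0.05)
      manual <- manual + 1L
  }
  expect_equal(nrow(ret2), manual)
})

test_that("moderated t matches limma and degenerates correctly", {
  skip_if_not_installed("limma")
  set.seed(99)
  n1 <- 6L; n2 <- 5L
  # heterogeneous variances so the prior df is finite
  s2_true <- 1 / rgamma(50, shape = 3, rate = 3)
  X <- t(vapply(s2_true, function(v)
    c(rnorm(n1, 0.3, sqrt(v)), rnorm(n2, 0, sqrt(v))), numeric(n1 + n2)))
  dimnames(X) <- list(paste0("f", 1:50), paste0("s", 1:(n1 + n2)))
  g <- rep(c("sensitive", "resistant"), c(n1, n2))
  res <- moderated_ttest(X, factor(g, levels = c("sensitive", "resistant")))

  design <- cbind(Intercept = 1, sens = as.numeric(g == "sensitive"))
  fit <- limma::eBayes(limma::lmFit(X, design))
  expect_equal(attr(res, "d0"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(res, "s0_sq"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(res$coef, unname(fit$coefficients[, "sens"]), tolerance = 1e-9)
  expect_equal(res$t_moderated, unname(fit$t[, "sens"]), tolerance = 1e-6)
  expect_equal(res$p_raw, unname(fit$p.value[, "sens"]), tolerance = 1e-6)

  # independent moment-estimator oracle
  mom <- oracle_fdist_moments(res$s2, n1 + n2 - 2)
  expect_equal(attr(res, "d0"), mom$d0, tolerance = 1e-6)
  expect_equal(attr(res, "s0_sq"), mom$s0_sq, tolerance = 1e-6)

  # null feature: equal group means give t ~ 0
  Xn <- X
  Xn[1, ] <- c(rep(1, n1), rep(1, n2)) + rnorm(n1 + n2, sd = 1e-8)
  # with d0 -> 0 the posterior variance is the per-feature variance:
  # check the degeneracy on the formula directly
  d0 <- 0
  s2_post <- (d0 * attr(res, "s0_sq") + res$df_residual * res$s2) /
    (d0 + res$df_residual)
  expect_equal(s2_post, res$s2)

  # moderated t keeps the sign of the contrast
  expect_true(all(sign(res$t_moderated) == sign(res$coef)))
  # adjusted p dominates raw p
  expect_true(all(res$p_adj >= res$p_raw - 1e-15))
})

test_that("moderated t handles exact null and missing-data features", {
  set.seed(5)
  X <- matrix(rnorm(200), 20, 10,
              dimnames = list(paste0("f", 1:20), paste0("s", 1:10)))
  X[1, ] <- rep(2, 10)                       # constant: zero coef, zero var
  X[2, 6:10] <- X[2, 1:5]                    # exactly equal group profiles
  X[3, c(1, 2, 6)] <- NA                     # partial missingness
  g <- factor(rep(c("a", "b"), each = 5), levels = c("a", "b"))
  res <- moderated_ttest(X, g)
  expect_equal(res$coef[1], 0)
  expect_equal(res$t_moderated[1], 0)
  expect_equal(res$coef[2], 0)
  expect_equal(res$p_raw[2], 1)
  expect_equal(res$df_residual[3], 7 - 2)    # 3 + 4 available samples
  expect_error(moderated_ttest(X[1, , drop = FALSE], g), "2 features")
})

test_that("BH adjustment matches the closed form and the step-up oracle", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(benjamini_hochberg(0.42), 0.42)
  expect_error(benjamini_hochberg(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(8)
  for (i in 1:10) {
    p <- runif(sample(3:40, 1))
    expect_equal(benjamini_hochberg(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("EMDR identification is antisymmetric, deterministic and guarded", {
  panel <- small_panel()
  om <- center_scale_features(average_replicates(panel$omics))
  resp <- panel$responses  # already on [0,1]
  e1 <- identify_emdr(om, resp, "drug01", seed = 31L,
                      params = emdr_params(min_group_size = 4L))
  expect_gt(length(e1$sensitivity) + length(e1$resistance), 0L)
  expect_length(intersect(e1$sensitivity, e1$resistance), 0L)
  expect_true(all(e1$support$support >= emdr_params()$consistency))
  expect_true(all(e1$support$support <= 1))
  expect_true(all(e1$support$feature %in% rownames(om$values)))

  # determinism
  e2 <- identify_emdr(om, resp, "drug01", seed = 31L,
                      params = emdr_params(min_group_size = 4L))
  expect_identical(e1, e2)

  # sign-flipped responses swap sensitivity and resistance exactly
  flipped <- resp
  flipped$aac <- 1 - flipped$aac
  e3 <- identify_emdr(om, flipped, "drug01", seed = 31L,
                      params = emdr_params(min_group_size = 4L))
  expect_setequal(e3$sensitivity, e1$resistance)
  expect_setequal(e3$resistance, e1$sensitivity)

  # a constant feature can never be a marker
  omc <- om
  omc$values["f0100", ] <- 0
  e4 <- identify_emdr(omc, resp, "drug01", seed = 31L,
                      params = emdr_params(min_group_size = 4L))
  expect_false("f0100" %in% c(e4$sensitivity, e4$resistance))

  # too few observations is a skip, not an error
  tiny <- resp
  tiny$aac <- tiny$aac[, 1:4]
  e5 <- identify_emdr(om, tiny, "drug01", seed = 31L)
  expect_match(e5$status, "skipped")
  expect_length(e5$sensitivity, 0L)
})

test_that("catalog discovery is invariant to drug order and serializes", {
  panel <- small_panel()
  om <- center_scale_features(average_replicates(panel$omics))
  resp <- panel$responses
  params <- emdr_params(min_group_size = 4L)
  cat1 <- discover_emdr(om, resp, params = params, seed = 101L)
  cat2 <- discover_emdr(om, resp, params = params, seed = 101L,
                        drugs = rev(rownames(resp$aac)))
  expect_identical(cat1[["drug01"]], cat2[["drug01"]])
  expect_identical(cat1[["drug02"]], cat2[["drug02"]])

  path <- tempfile(fileext = ".json")
  write_emdr_catalog(cat1, path)
  back <- read_emdr_catalog(path)
  expect_setequal(back[["drug01"]]$sensitivity, cat1[["drug01"]]$sensitivity)
  expect_equal(back[["drug01"]]$n_retained, cat1[["drug01"]]$n_retained)
})
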