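#' Partition cell lines into training and validation sets
#'
#' Stratified split on the response level: cell lines are binned by quantiles
#' of their mean AAC (caret's numeric-outcome partition behavior) and sampled
#' within bins, so training and validation span the response range.
#' Deterministic given the seed.
#'
#' @param cell_lines Character vector of cell-line ids.
#' @param responses A [drug_response_table()] covering the lines.
#' @param ratio Training fraction (default 0.8).
#' @param seed Integer seed.
#' @return `list(train =, validation =)` of cell-line ids.
#' @export
partition_cell_lines <- function(cell_lines, responses, ratio = 0.8, seed = 1L) {
  if (length(cell_lines) < 10L) stop("need at least 10 cell lines to partition")
  mean_aac <- colMeans(responses$aac[, cell_lines, drop = FALSE], na.rm = TRUE)
  set.seed(seed)
  idx <- caret::createDataPartition(mean_aac, p = ratio, list = FALSE)[, 1L]
  list(train = cell_lines[idx], validation = cell_lines[-idx])
}

# ---- algorithm registry ----------------------------------------------------

# two-hidden-layer perceptron (tanh units, linear output) trained by BFGS
# with analytic gradients and an L2 weight penalty (biases unpenalized)
mlp2_unpack <- function(w, p, h1, h2) {
  i <- 0L
  W1 <- matrix(w[i + seq_len(p * h1)], p, h1); i <- i + p * h1
  b1 <- w[i + seq_len(h1)]; i <- i + h1
  W2 <- matrix(w[i + seq_len(h1 * h2)], h1, h2); i <- i + h1 * h2
  b2 <- w[i + seq_len(h2)]; i <- i + h2
  w3 <- w[i + seq_len(h2)]; i <- i + h2
  b3 <- w[i + 1L]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, w3 = w3, b3 = b3)
}

mlp2_objective <- function(X, y, h1, h2, decay) {
  p <- ncol(X); n <- nrow(X)
  fwd <- function(pa) {
    a1 <- tanh(sweep(X %*% pa$W1, 2L, pa$b1, "+"))
    a2 <- tanh(sweep(a1 %*% pa$W2, 2L, pa$b2, "+"))
    list(a1 = a1, a2 = a2, yhat = drop(a2 %*% pa$w3) + pa$b3)
  }
  list(
    n_par = p * h1 + h1 + h1 * h2 + h2 + h2 + 1L,
    loss = function(w) {
      pa <- mlp2_unpack(w, p, h1, h2); f <- fwd(pa)
      sum((f$yhat - y)^2) / (2 * n) +
        decay / 2 * (sum(pa$W1^2) + sum(pa$W2^2) + sum(pa$w3^2))
    },
    grad = function(w) {
      pa <- mlp2_unpack(w, p, h1, h2); f <- fwd(pa)
      r <- (f$yhat - y) / n
      dw3 <- drop(crossprod(f$a2, r)) + decay * pa$w3
      db3 <- sum(r)
      dz2 <- (r %o% pa$w3) * (1 - f$a2^2)
      dW2 <- crossprod(f$a1, dz2) + decay * pa$W2
      db2 <- colSums(dz2)
      dz1 <- (dz2 %*% t(pa$W2)) * (1 - f$a1^2)
      dW1 <- crossprod(X, dz1) + decay * pa$W1
      db1 <- colSums(dz1)
      c(as.vector(dW1), db1, as.vector(dW2), db2, dw3, db3)
    })
}

fit_mlp2 <- function(X, y, sizes = c(8L, 4L), decay = 0.01, maxit = 200L) {
  obj <- mlp2_objective(X, y, sizes[1L], sizes[2L], decay)
  w0 <- stats::runif(obj$n_par, -0.5, 0.5) / sqrt(ncol(X))
  opt <- stats::optim(w0, obj$loss, obj$grad, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-10))
  structure(list(pars = mlp2_unpack(opt$par, ncol(X), sizes[1L], sizes[2L]),
                 sizes = sizes),
            class = "emdrank_mlp2")
}

predict_mlp2 <- function(model, X) {
  a1 <- tanh(sweep(X %*% model$pars$W1, 2L, model$pars$b1, "+"))
  a2 <- tanh(sweep(a1 %*% model$pars$W2, 2L, model$pars$b2, "+"))
  drop(a2 %*% model$pars$w3) + model$pars$b3
}

fit_pcr <- function(X, y, ncomp) {
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  nc <- min(ncomp, ncol(pc$x), nrow(X) - 1L)
  sc <- pc$x[, seq_len(nc), drop = FALSE]
  co <- stats::lm.fit(cbind(1, sc), y)$coefficients
  co[is.na(co)] <- 0
  list(center = pc$center, rotation = pc$rotation[, seq_len(nc), drop = FALSE],
       coef = co)
}

predict_pcr <- function(model, X) {
  sc <- sweep(X, 2L, model$center) %*% model$rotation
  drop(cbind(1, sc) %*% model$coef)
}

#' The per-drug regression algorithm roster
#'
#' Eight regressors are trained per drug on normalized D features:
#' `random_forest`, `rule_committee` (gradient-boosted trees),
#' `bayes_glm` (ridge-penalized GLM), `pls`, `pcr`, `svr` (RBF),
#' `mlp_single` (one hidden layer) and `mlp_deep` (two hidden layers).
#' Each carries a small default hyperparameter grid searched by cross
#' validation; `pls` and `pcr` are tuned by leave-one-out CV, everything else
#' by repeated 10-fold CV (3 repeats) on RMSE.
#'
#' @return Named list; each element has `grid(p, n)` returning a data frame of
#'   hyperparameter rows, `fit(X, y, h)` and `predict(model, X)`.
#' @export
algorithm_registry <- function() {
  list(
    random_forest = list(
      grid = function(p, n) data.frame(
        mtry = unique(pmax(1L, c(floor(sqrt(p)), floor(p / 3))))),
      fit = function(X, y, h)
        randomForest::randomForest(X, y, mtry = h$mtry, ntree = 500L),
      predict = function(m, X) unname(stats::predict(m, X))),
    rule_committee = list(
      grid = function(p, n) expand.grid(nrounds = c(50L, 150L),
                                        max_depth = c(2L, 3L)),
      fit = function(X, y, h)
        xgboost::xgboost(x = X, y = y, nrounds = h$nrounds,
                         max_depth = h$max_depth, learning_rate = 0.1,
                         objective = "reg:squarederror",
                         nthreads = 1L, verbosity = 0L),
      predict = function(m, X) unname(stats::predict(m, X))),
    bayes_glm = list(
      grid = function(p, n) data.frame(lambda = c(0.01, 0.1, 1)),
      fit = function(X, y, h)
        glmnet::glmnet(X, y, alpha = 0, lambda = c(10, 1, 0.1, 0.01, 0.001)),
      predict = function(m, X, h) drop(stats::predict(m, X, s = h$lambda))),
    pls = list(
      grid = function(p, n) data.frame(ncomp = seq_len(min(6L, p, n - 2L))),
      fit = function(X, y, h)
        mixOmics::pls(X, y, ncomp = h$ncomp, mode = "regression"),
      predict = function(m, X, h)
        unname(stats::predict(m, X)$predict[, 1L, h$ncomp])),
    pcr = list(
      grid = function(p, n) data.frame(ncomp = seq_len(min(6L, p, n - 2L))),
      fit = function(X, y, h) fit_pcr(X, y, h$ncomp),
      predict = function(m, X) predict_pcr(m, X)),
    svr = list(
      grid = function(p, n) data.frame(cost = c(1, 10)),
      fit = function(X, y, h)
        e1071::svm(X, y, type = "eps-regression", kernel = "radial",
                   cost = h$cost),
      predict = function(m, X) unname(stats::predict(m, X))),
    mlp_single = list(
      grid = function(p, n) expand.grid(size = c(3L, 5L), decay = c(0.01, 0.1)),
      fit = function(X, y, h)
        nnet::nnet(X, y, size = h$size, decay = h$decay, linout = TRUE,
                   maxit = 500L, trace = FALSE),
      predict = function(m, X) drop(stats::predict(m, X))),
    mlp_deep = list(
      grid = function(p, n) data.frame(decay = c(0.01, 0.1)),
      fit = function(X, y, h) fit_mlp2(X, y, sizes = c(8L, 4L), decay = h$decay),
      predict = function(m, X) predict_mlp2(m, X))
  )
}

alg_predict <- function(alg, model, X, h) {
  f <- alg$predict
  if (length(formals(f)) >= 3L) f(model, X, h) else f(model, X)
}

rmse <- function(obs, pred) sqrt(mean((obs - pred)^2))

cv_resamples <- function(y, algorithm, k = 10L, repeats = 3L) {
  if (algorithm %in% c("pls", "pcr")) {
    lapply(seq_along(y), function(i) setdiff(seq_along(y), i))
  } else {
    unname(caret::createMultiFolds(y, k = k, times = repeats))
  }
}

#' Train the model roster for one drug
#'
#' For each algorithm: grid search over its default hyperparameter grid,
#' scoring each point by mean held-out RMSE over the resamples (repeated
#' 10-fold CV with 3 repeats; leave-one-out for `pls`/`pcr`), then a final
#' refit of the winning point on all training lines. An algorithm that fails
#' (e.g. non-convergence) is marked unavailable without affecting the others.
#'
#' @param X Numeric matrix, training cell lines x normalized D predictors
#'   (complete, no `NA`).
#' @param y Numeric AAC vector (length `nrow(X)`).
#' @param roster Algorithm names (default: all of [algorithm_registry()]).
#' @param cv_k,cv_repeats Fold count and repeats for the repeated CV.
#' @param seed Integer seed (per-algorithm streams derived from it).
#' @return Named list per algorithm: `fit`, `hyper`, `cv_rmse` (mean),
#'   `cv_resample_rmse` (per-resample), `status`.
#' @export
train_drug_models <- function(X, y, roster = names(algorithm_registry()),
                              cv_k = 10L, cv_repeats = 3L, seed = 1L) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  if (anyNA(X)) stop("X must be complete after coverage filtering")
  if (nrow(X) < 10L) stop("need at least 10 training lines")
  reg <- algorithm_registry()
  unknown <- setdiff(roster, names(reg))
  if (length(unknown)) stop("unknown algorithms: ", paste(unknown, collapse = ", "))
  out <- list()
  for (a in roster) {
    alg <- reg[[a]]
    res <- tryCatch({
      set.seed(derive_seed(seed, paste0("cv-", a)))
      folds <- cv_resamples(y, a, k = cv_k, repeats = cv_repeats)
      grid <- alg$grid(ncol(X), nrow(X))
      scores <- matrix(NA_real_, length(folds), nrow(grid))
      for (gi in seq_len(nrow(grid))) {
        h <- grid[gi, , drop = FALSE]
        for (fi in seq_along(folds)) {
          tr <- folds[[fi]]; te <- setdiff(seq_along(y), tr)
          set.seed(derive_seed(seed, sprintf("%s-%d-%d", a, gi, fi)))
          m <- alg$fit(X[tr, , drop = FALSE], y[tr], h)
          scores[fi, gi] <- rmse(y[te],
                                 alg_predict(alg, m, X[te, , drop = FALSE], h))
        }
      }
      mean_rmse <- colMeans(scores)
      best <- which.min(mean_rmse)
      h <- grid[best, , drop = FALSE]
      set.seed(derive_seed(seed, paste0(a, "-final")))
      fit <- alg$fit(X, y, h)
      list(fit = fit, hyper = as.list(h), cv_rmse = mean_rmse[best],
           cv_resample_rmse = scores[, best], status = "ok")
    }, error = function(e)
      list(fit = NULL, hyper = NULL, cv_rmse = NA_real_,
           cv_resample_rmse = NULL,
           status = paste0("unavailable: ", conditionMessage(e))))
    out[[a]] <- res
  }
  out
}

#' Train the full per-drug model ensemble
#'
#' Builds, for every drug with a predictor set, the feature matrix of
#' normalized D values over the training cell lines, drops predictors or lines
#' with missing coverage, and trains the roster via [train_drug_models()].
#'
#' @param d_norm Normalized training `drug_distance_matrix` (after
#'   [apply_minmax()]).
#' @param responses Scaled [drug_response_table()].
#' @param predictor_sets Named list from [select_all_predictors()].
#' @param train_lines Training cell-line ids.
#' @param roster,cv_k,cv_repeats See [train_drug_models()].
#' @param seed Master seed; per-drug seeds derived from drug ids.
#' @param verbose Log per-drug progress.
#' @return A `drug_model_ensemble`: per-drug models plus the partition,
#'   normalization parameters and seeds needed to predict new samples.
#' @export
train_ensemble <- function(d_norm, responses, predictor_sets, train_lines,
                           roster = names(algorithm_registry()),
                           cv_k = 10L, cv_repeats = 3L, seed = 1L,
                           verbose = FALSE) {
  drugs <- names(predictor_sets)
  entries <- list()
  for (d in drugs) {
    preds <- predictor_sets[[d]]$predictors$drug
    Xall <- t(d_norm$D[preds, intersect(train_lines, colnames(d_norm$D)),
                       drop = FALSE])
    keep_pred <- colSums(is.na(Xall)) == 0L
    X <- Xall[, keep_pred, drop = FALSE]
    y <- responses$aac[d, rownames(X)]
    ok <- !is.na(y)
    X <- X[ok, , drop = FALSE]; y <- y[ok]
    ent <- tryCatch({
      if (ncol(X) < 2L) stop("fewer than 2 complete predictors")
      models <- train_drug_models(X, y, roster = roster, cv_k = cv_k,
                                  cv_repeats = cv_repeats,
                                  seed = derive_seed(seed, d))
      list(target = d, predictors = colnames(X), models = models,
           train_lines = rownames(X), n_train = nrow(X), status = "ok")
    }, error = function(e)
      list(target = d, predictors = character(0), models = list(),
           n_train = nrow(X), status = paste0("failed: ", conditionMessage(e))))
    msg(verbose, "trained %s [%s]", d, ent$status)
    entries[[d]] <- ent
  }
  structure(list(drugs = entries, roster = roster,
                 norm_params = d_norm$norm_params,
                 cv = list(k = cv_k, repeats = cv_repeats), seed = seed),
            class = "drug_model_ensemble")
}

#' @export
print.drug_model_ensemble <- function(x, ...) {
  ok <- sum(vapply(x$drugs, function(e) identical(e$status, "ok"), logical(1)))
  cat(sprintf("drug_model_ensemble: %d/%d drugs trained, roster: %s\n",
              ok, length(x$drugs), paste(x$roster, collapse = ", ")))
  invisible(x)
}

predict_one <- function(entry, algorithm, Xnew) {
  m <- entry$models[[algorithm]]
  if (is.null(m) || !identical(m$status, "ok")) return(NULL)
  reg <- algorithm_registry()
  alg <- reg[[algorithm]]
  pred <- rep(NA_real_, nrow(Xnew))
  complete <- rowSums(is.na(Xnew)) == 0L
  if (any(complete))
    pred[complete] <- alg_predict(alg, m$fit,
                                  Xnew[complete, , drop = FALSE],
                                  as.data.frame(m$hyper))
  pred
}

#' Predict drug responses for new samples
#'
#' New-sample D values are normalized with the stored training min-max
#' parameters, fed through the requested fitted regressor (or the consensus),
#' and clipped to the `[0, 1]` AAC scale. Samples lacking any required
#' predictor D are reported missing for that drug.
#'
#' @param ensemble A `drug_model_ensemble`.
#' @param new_distances Raw (unnormalized) `drug_distance_matrix` for the new
#'   samples.
#' @param algorithm One roster algorithm or `"consensus"` (mean of
#'   `random_forest`, `pcr` and `pls`, requiring at least 2 members).
#' @param members Consensus member algorithms.
#' @return Numeric matrix drugs x samples of predicted AAC (class attribute
#'   `prediction_table`), clipped to `[0, 1]`.
#' @export
predict_responses <- function(ensemble, new_distances,
                              algorithm = "random_forest",
                              members = c("random_forest", "pcr", "pls")) {
  if (!identical(algorithm, "consensus") &&
      !algorithm %in% ensemble$roster)
    stop("unknown algorithm: ", algorithm)
  dn <- apply_minmax(new_distances, ensemble$norm_params)
  samples <- colnames(dn$D)
  drugs <- names(ensemble$drugs)
  out <- matrix(NA_real_, length(drugs), length(samples),
                dimnames = list(drugs, samples))
  for (d in drugs) {
    entry <- ensemble$drugs[[d]]
    if (!identical(entry$status, "ok")) next
    miss_pred <- setdiff(entry$predictors, rownames(dn$D))
    if (length(miss_pred)) next
    Xnew <- t(dn$D[entry$predictors, , drop = FALSE])
    if (identical(algorithm, "consensus")) {
      mat <- vapply(members, function(a) {
        p <- predict_one(entry, a, Xnew)
        if (is.null(p)) rep(NA_real_, nrow(Xnew)) else p
      }, numeric(nrow(Xnew)))
      n_avail <- rowSums(!is.na(mat))
      pred <- ifelse(n_avail >= 2L, rowMeans(mat, na.rm = TRUE), NA_real_)
    } else {
      pred <- predict_one(entry, algorithm, Xnew)
      if (is.null(pred)) next
    }
    out[d, ] <- pmin(pmax(pred, 0), 1)
  }
  structure(out, class = c("prediction_table", "matrix", "array"),
            algorithm = algorithm, seed = ensemble$seed)
}

#' Consensus prediction for a single sample's D profile
#'
#' Unweighted mean of the member-model predictions (default random forest,
#' PCR and PLS), requiring at least two available members; clipped to
#' `[0, 1]`.
#'
#' @param ensemble A `drug_model_ensemble`.
#' @param sample_D Named numeric vector of the sample's raw D values (names =
#'   drug ids).
#' @param members Member algorithms.
#' @return Named numeric vector of predicted AAC per drug (`NA` when fewer
#'   than 2 members are available).
#' @export
consensus_prediction <- function(ensemble, sample_D,
                                 members = c("random_forest", "pcr", "pls")) {
  dm <- structure(list(D = matrix(sample_D, ncol = 1,
                                  dimnames = list(names(sample_D), "sample")),
                       norm_params = NULL),
                  class = "drug_distance_matrix")
  predict_responses(ensemble, dm, algorithm = "consensus",
                    members = members)[, 1L]
}

#' Stratify samples by the mean predicted response
#'
#' Samples predicted above the mean predicted AAC are labelled `"high"`
#' (predicted sensitive), the rest `"low"` — the cutoff used to split patient
#' cohorts for survival comparison.
#'
#' @param predictions Named numeric vector of per-sample predicted AAC for one
#'   drug.
#' @return Named character vector of `"high"` / `"low"` labels.
#' @export
stratify_by_mean_prediction <- function(predictions) {
  obs <- predictions[!is.na(predictions)]
  if (length(obs) < 2L) stop("need at least 2 samples to stratify")
  cut <- mean(obs)
  labels <- ifelse(predictions > cut, "high", "low")
  labels[is.na(predictions)] <- NA_character_
  labels
}
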