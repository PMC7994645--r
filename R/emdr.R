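#' Split cell lines into sensitive and resistant populations at the median AAC
#'
#' Cell lines with response above the drug's median AAC are labelled sensitive,
#' below median resistant. Lines exactly at the median go to the sensitive
#' group (fixed, documented tie rule).
#'
#' @param aac_row Named numeric vector of one drug's responses across cell
#'   lines (`NA` allowed).
#' @param min_group_size Minimum observed responses required per group half
#'   (the split needs at least `2 * min_group_size` observations).
#' @return `list(sensitive =, resistant =)` of cell-line ids.
#' @export
split_sensitive_resistant <- function(aac_row, min_group_size = 6L) {
  obs <- aac_row[!is.na(aac_row)]
  if (length(obs) < 2L * min_group_size)
    stop(sprintf("too few observed responses (%d < %d)",
                 length(obs), 2L * min_group_size))
  med <- stats::median(obs)
  sens <- names(obs)[obs >= med]
  res <- names(obs)[obs < med]
  if (length(sens) < 2L || length(res) < 2L)
    stop("degenerate median split (a group has fewer than 2 members)")
  list(sensitive = sens, resistant = res)
}

#' Build leave-one-fold-out resample subsets of a cell-line group
#'
#' Partitions the members into `k` folds (sizes differing by at most one) and
#' returns the `k` complementary subsets, each holding roughly `(k-1)/k` of the
#' members. Deterministic given the seed.
#'
#' @param members Character vector of cell-line ids.
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return List of `k` character vectors.
#' @export
make_resample_groups <- function(members, k = 10L, seed = 1L) {
  if (length(members) < 2L) stop("need at least 2 members to resample")
  k <- min(k, length(members))   # no more folds than members
  set.seed(seed)
  idx <- caret::createMultiFolds(seq_along(members), k = k, times = 1L)
  lapply(unname(idx), function(i) members[i])
}

# Welch t p-value robust to zero-variance groups: identical constants give
# p = 1, separated constants p = 0 (the limit of the test statistic).
welch_p <- function(x, y) {
  p <- tryCatch(stats::t.test(x, y)$p.value, error = function(e) NA_real_)
  if (is.na(p)) p <- if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
  p
}

#' Screen sensitive-resistant group pairs by AAC separation
#'
#' Every sensitive subset is compared with every resistant subset by a
#' two-sided Welch t-test on their AAC values; only pairs whose response
#' distributions differ at `alpha` are retained for marker contrasts.
#'
#' @param sens_groups,res_groups Lists of cell-line subsets from
#'   [make_resample_groups()].
#' @param aac_row Named numeric responses for the drug.
#' @param alpha Retention threshold on the Welch p-value (default 0.05).
#' @return Data frame of retained pairs with columns `i`, `j`, `p`.
#' @export
screen_group_pairs <- function(sens_groups, res_groups, aac_row, alpha = 0.05) {
  grid <- expand.grid(i = seq_along(sens_groups), j = seq_along(res_groups))
  grid$p <- mapply(function(i, j)
    welch_p(aac_row[sens_groups[[i]]], aac_row[res_groups[[j]]]),
    grid$i, grid$j)
  grid[grid$p < alpha, , drop = FALSE]
}

# Newton inversion of the trigamma function (x = trigamma(y), solve for y)
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (iter in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Empirical-Bayes moderated two-group t-test
#'
#' Ordinary two-sample contrasts (sensitive minus resistant) with per-feature
#' pooled variances shrunk towards a common prior estimated across features by
#' closed-form method-of-moments on `log(s^2)` (digamma/trigamma inversion).
#' The moderated t uses `d0 + df` degrees of freedom, where `d0` is the prior
#' degrees of freedom; `d0 = Inf` collapses every posterior variance to the
#' common prior `s0^2`.
#'
#' @param values Numeric matrix, features x samples (may contain `NA`).
#' @param group_labels Factor or character of length `ncol(values)` with
#'   exactly two levels; the first level is the "sensitive" group whose mean
#'   enters the contrast positively.
#' @return A data frame (class `moderated_test_result`) with per-feature
#'   `coef`, `s2`, `df_residual`, `t_moderated`, `p_raw`, `p_adj` and
#'   attributes `d0` and `s0_sq`.
#' @export
moderated_ttest <- function(values, group_labels) {
  stopifnot(is.matrix(values))
  if (nrow(values) < 2L) stop("moderation needs at least 2 features")
  g <- factor(group_labels)
  if (nlevels(g) != 2L) stop("exactly two group labels required")
  lv <- levels(g)
  x1 <- values[, g == lv[1L], drop = FALSE]
  x2 <- values[, g == lv[2L], drop = FALSE]
  if (ncol(x1) < 2L || ncol(x2) < 2L) stop("need >=2 samples per group")

  n1 <- rowSums(!is.na(x1)); n2 <- rowSums(!is.na(x2))
  ok <- n1 >= 2L & n2 >= 2L
  m1 <- rowMeans(x1, na.rm = TRUE); m2 <- rowMeans(x2, na.rm = TRUE)
  ss1 <- rowSums((x1 - m1)^2, na.rm = TRUE)
  ss2 <- rowSums((x2 - m2)^2, na.rm = TRUE)
  df <- n1 + n2 - 2
  s2 <- (ss1 + ss2) / df
  coef <- m1 - m2
  coef[!ok] <- NA_real_; s2[!ok] <- NA_real_; df[!ok] <- NA_real_

  # moment estimation of (d0, s0^2) on log(s2), features with s2 > 0 only
  use <- ok & s2 > 0
  if (sum(use) < 2L) stop("too few features with positive residual variance")
  z <- log(s2[use])
  e <- z - digamma(df[use] / 2) + log(df[use] / 2)
  emean <- mean(e)
  nuse <- length(e)
  evar <- mean((e - emean)^2) * nuse / (nuse - 1) - mean(trigamma(df[use] / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }

  s2_post <- if (is.infinite(d0)) rep(s0_sq, length(s2)) else
    (d0 * s0_sq + df * s2) / (d0 + df)
  tt <- coef / sqrt(s2_post * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs(tt), df = d0 + df)
  res <- data.frame(
    feature = rownames(values) %||% as.character(seq_len(nrow(values))),
    coef = coef, s2 = s2, df_residual = df,
    t_moderated = tt, p_raw = p,
    p_adj = benjamini_hochberg(p),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "d0") <- d0
  attr(res, "s0_sq") <- s0_sq
  class(res) <- c("moderated_test_result", "data.frame")
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` passed through).
#' @return Adjusted p-values (q-values), capped at 1.
#' @export
benjamini_hochberg <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Default parameters for EMDR discovery
#'
#' @param k Folds per population (10 folds giving 10 leave-one-fold-out
#'   subsets per side, hence `k * k` group pairs).
#' @param fold_threshold Contrast-coefficient magnitude a feature must reach,
#'   on the normalized abundance scale (default 0.8).
#' @param p_threshold Significance threshold within a repeat (default 0.05).
#' @param consistency Fraction of retained repeats in which both thresholds
#'   must hold (default 0.8).
#' @param screen_alpha Welch p cutoff for retaining group pairs (default 0.05).
#' @param use_adjusted_p Threshold BH-adjusted p within repeats instead of
#'   raw p (default `FALSE`). The fold-pair consistency rule (both thresholds
#'   in >= 80% of ~100 resampled contrasts) is the procedure's
#'   multiple-testing control, so raw p within each repeat is the default;
#'   per-repeat BH across features is available but is severely conservative
#'   on feature spaces of realistic size.
#' @param min_group_size Minimum split half-size, see
#'   [split_sensitive_resistant()].
#' @param min_retained Below this many retained pairs the catalog entry is
#'   flagged low-support (default 10).
#' @return Named list of parameters.
#' @export
emdr_params <- function(k = 10L, fold_threshold = 0.8, p_threshold = 0.05,
                        consistency = 0.8, screen_alpha = 0.05,
                        use_adjusted_p = FALSE, min_group_size = 6L,
                        min_retained = 10L) {
  list(k = as.integer(k), fold_threshold = fold_threshold,
       p_threshold = p_threshold, consistency = consistency,
       screen_alpha = screen_alpha, use_adjusted_p = isTRUE(use_adjusted_p),
       min_group_size = as.integer(min_group_size),
       min_retained = as.integer(min_retained))
}

skipped_entry <- function(reason) {
  list(sensitivity = character(0), resistance = character(0),
       support = data.frame(feature = character(0), side = character(0),
                            support = numeric(0), mean_coef = numeric(0),
                            stringsAsFactors = FALSE),
       n_retained = 0L, status = paste0("skipped: ", reason))
}

#' Identify empirical markers of drug response for one drug
#'
#' Runs the full discovery chain: median-AAC split into sensitive/resistant
#' populations, seeded leave-one-fold-out resampling of each side, Welch
#' screening of the `k x k` group pairs on AAC, then a moderated t contrast of
#' the omics matrix per retained pair. A feature becomes a sensitivity marker
#' if its contrast coefficient is `>= +fold_threshold` with adjusted
#' `p < p_threshold` in at least `consistency` of the retained pairs; a
#' resistance marker under the mirrored rule.
#'
#' @param omics Cell-line-averaged, normalized [omics_matrix()].
#' @param responses A scaled [drug_response_table()].
#' @param drug Drug id present in `responses`.
#' @param params See [emdr_params()].
#' @param seed Integer seed for the resampling.
#' @return A catalog entry: `list(sensitivity, resistance, support,
#'   n_retained, status)`.
#' @export
identify_emdr <- function(omics, responses, drug, params = emdr_params(),
                          seed = 1L) {
  if (!drug %in% rownames(responses$aac)) stop("unknown drug: ", drug)
  common <- intersect(colnames(omics$values), colnames(responses$aac))
  aac_row <- responses$aac[drug, common]
  split <- tryCatch(
    split_sensitive_resistant(aac_row, params$min_group_size),
    error = function(e) e)
  if (inherits(split, "error")) return(skipped_entry(conditionMessage(split)))

  sens_groups <- make_resample_groups(split$sensitive, params$k,
                                      seed = derive_seed(seed, "sensitive"))
  res_groups <- make_resample_groups(split$resistant, params$k,
                                     seed = derive_seed(seed, "resistant"))
  retained <- screen_group_pairs(sens_groups, res_groups, aac_row,
                                 params$screen_alpha)
  if (nrow(retained) == 0L) return(skipped_entry("no separable repeats"))

  nf <- nrow(omics$values)
  hits_sens <- numeric(nf); hits_res <- numeric(nf); coef_sum <- numeric(nf)
  tested <- numeric(nf)
  for (r in seq_len(nrow(retained))) {
    smp_s <- sens_groups[[retained$i[r]]]
    smp_r <- res_groups[[retained$j[r]]]
    sub <- omics$values[, c(smp_s, smp_r), drop = FALSE]
    lab <- factor(rep(c("sensitive", "resistant"),
                      c(length(smp_s), length(smp_r))),
                  levels = c("sensitive", "resistant"))
    mt <- moderated_ttest(sub, lab)
    pcol <- if (params$use_adjusted_p) mt$p_adj else mt$p_raw
    okf <- !is.na(mt$coef)
    tested <- tested + okf
    coef_sum <- coef_sum + ifelse(okf, mt$coef, 0)
    hits_sens <- hits_sens +
      (okf & mt$coef >= params$fold_threshold & pcol < params$p_threshold)
    hits_res <- hits_res +
      (okf & mt$coef <= -params$fold_threshold & pcol < params$p_threshold)
  }
  n_ret <- nrow(retained)
  frac_sens <- hits_sens / n_ret
  frac_res <- hits_res / n_ret
  feats <- rownames(omics$values)
  is_sens <- frac_sens >= params$consistency
  is_res <- frac_res >= params$consistency
  support <- data.frame(
    feature = c(feats[is_sens], feats[is_res]),
    side = rep(c("sensitivity", "resistance"), c(sum(is_sens), sum(is_res))),
    support = c(frac_sens[is_sens], frac_res[is_res]),
    mean_coef = c(coef_sum[is_sens] / pmax(tested[is_sens], 1),
                  coef_sum[is_res] / pmax(tested[is_res], 1)),
    stringsAsFactors = FALSE)
  list(sensitivity = feats[is_sens], resistance = feats[is_res],
       support = support, n_retained = n_ret,
       status = if (n_ret < params$min_retained) "low_support" else "ok")
}

#' Discover an EMDR catalog across drugs
#'
#' Applies [identify_emdr()] to every drug (or a subset); per-drug seeds are
#' derived from the master seed and the drug id, so the catalog is invariant to
#' drug ordering.
#'
#' @param omics Cell-line-averaged, normalized [omics_matrix()].
#' @param responses A scaled [drug_response_table()].
#' @param params See [emdr_params()].
#' @param seed Master seed.
#' @param drugs Drug ids (default: all rows of `responses`).
#' @param verbose Log per-drug marker counts.
#' @return An `emdr_catalog`: named list of catalog entries with the
#'   parameters stored as an attribute.
#' @export
discover_emdr <- function(omics, responses, params = emdr_params(), seed = 1L,
                          drugs = rownames(responses$aac), verbose = FALSE) {
  entries <- lapply(drugs, function(d) {
    e <- identify_emdr(omics, responses, d, params,
                       seed = derive_seed(seed, d))
    msg(verbose, "EMDR %s: %d sensitivity, %d resistance [%s]",
        d, length(e$sensitivity), length(e$resistance), e$status)
    e
  })
  names(entries) <- drugs
  structure(entries, class = "emdr_catalog", params = params, seed = seed)
}

#' Write an EMDR catalog to JSON
#' @param catalog An `emdr_catalog`.
#' @param path Output JSON path.
#' @export
write_emdr_catalog <- function(catalog, path) {
  obj <- lapply(catalog, function(e) list(
    sensitivity = e$sensitivity, resistance = e$resistance,
    support = e$support, n_retained = e$n_retained, status = e$status))
  jsonlite::write_json(list(params = attr(catalog, "params"),
                            seed = attr(catalog, "seed"), drugs = obj),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read an EMDR catalog from JSON
#' @param path JSON path written by [write_emdr_catalog()].
#' @return An `emdr_catalog`.
#' @export
read_emdr_catalog <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  entries <- lapply(obj$drugs, function(e) {
    sup <- e$support
    if (is.null(sup) || !length(sup)) sup <- skipped_entry("")$support
    list(sensitivity = as.character(unlist(e$sensitivity)),
         resistance = as.character(unlist(e$resistance)),
         support = as.data.frame(sup, stringsAsFactors = FALSE),
         n_retained = as.integer(e$n_retained), status = e$status)
  })
  structure(entries, class = "emdr_catalog",
            params = obj$params, seed = obj$seed)
}
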