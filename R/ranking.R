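#' Rank drugs within a sample by predicted efficacy
#'
#' @param predictions Named numeric vector, drug -> predicted AAC.
#' @return Character vector of drug ids, most effective (highest predicted
#'   AAC) first; ties break lexicographically by drug id.
#' @export
rank_drugs <- function(predictions) {
  if (length(predictions) < 2L) stop("need at least 2 drugs to rank")
  obs <- predictions[!is.na(predictions)]
  names(obs)[order(-obs, names(obs))]
}

spearman_rho_p <- function(x, y) {
  rho <- suppressWarnings(stats::cor(rank(x), rank(y)))
  n <- length(x)
  p <- if (is.na(rho)) NA_real_ else if (abs(rho) >= 1) 0 else
    2 * stats::pt(-abs(rho * sqrt((n - 2) / (1 - rho^2))), df = n - 2)
  c(rho = rho, p = p)
}

#' Evaluate predicted against measured drug responses
#'
#' Computes, per sample: the Spearman correlation (with BH-adjusted q values
#' across samples), RMSE and MSE of predicted vs measured AAC, and per drug
#' the absolute error and the difference between predicted and measured rank
#' positions (average ranks on ties, descending AAC = rank 1). Globally it
#' reports the proportions of predictions within the absolute-error cutoffs
#' and rank-difference cutoffs, plus the same proportions restricted to each
#' sample's top-`top_k` drugs.
#'
#' @param pred Prediction matrix drugs x samples (from
#'   [predict_responses()]).
#' @param measured A scaled [drug_response_table()].
#' @param top_k Top-ranked subset size (default 20).
#' @param anchor Whether the top-`top_k` subset is defined on `"measured"`
#'   (default) or `"predicted"` ranks.
#' @param error_cutoffs Absolute-error bins (AAC units).
#' @param rank_cutoffs Rank-difference bins (positions).
#' @param min_overlap Minimum overlapping drugs per sample (default 5; samples
#'   below are excluded with a warning).
#' @return A `ranking_report`: `list(per_sample, per_drug, summary)`.
#' @export
evaluate_predictions <- function(pred, measured, top_k = 20L,
                                 anchor = c("measured", "predicted"),
                                 error_cutoffs = c(0.05, 0.1, 0.15, 0.25),
                                 rank_cutoffs = c(20L, 50L),
                                 min_overlap = 5L) {
  anchor <- match.arg(anchor)
  samples <- intersect(colnames(pred), colnames(measured$aac))
  per_sample <- list(); per_drug <- list()
  for (b in samples) {
    drugs <- intersect(rownames(pred), rownames(measured$aac))
    p <- pred[drugs, b]; m <- measured$aac[drugs, b]
    ok <- !is.na(p) & !is.na(m)
    if (sum(ok) < min_overlap) {
      warning("sample '", b, "' has fewer than ", min_overlap,
              " overlapping drugs; excluded")
      next
    }
    p <- p[ok]; m <- m[ok]; drugs <- drugs[ok]
    rank_p <- rank(-p, ties.method = "average")
    rank_m <- rank(-m, ties.method = "average")
    sp <- spearman_rho_p(p, m)
    per_sample[[b]] <- data.frame(
      sample = b, n_drugs = length(p), rho = sp[["rho"]], p = sp[["p"]],
      rmse = rmse(m, p), mse = mean((m - p)^2), stringsAsFactors = FALSE)
    per_drug[[b]] <- data.frame(
      sample = b, drug = drugs, predicted = unname(p), measured = unname(m),
      abs_error = unname(abs(p - m)), rank_pred = unname(rank_p),
      rank_meas = unname(rank_m), rank_delta = unname(abs(rank_p - rank_m)),
      top_k = if (anchor == "measured") unname(rank_m <= top_k)
              else unname(rank_p <= top_k),
      stringsAsFactors = FALSE)
  }
  if (!length(per_sample)) stop("no sample has sufficient prediction overlap")
  ps <- do.call(rbind, per_sample); rownames(ps) <- NULL
  ps$q <- benjamini_hochberg(ps$p)
  pd <- do.call(rbind, per_drug); rownames(pd) <- NULL
  prop_within <- function(x, cutoffs, strict = FALSE)
    stats::setNames(vapply(cutoffs, function(cc)
      mean(if (strict) x < cc else x <= cc), numeric(1)),
      paste0("within_", cutoffs))
  top <- pd[pd$top_k, , drop = FALSE]
  summary <- list(
    n_samples = nrow(ps), n_pairs = nrow(pd),
    mean_rho = mean(ps$rho), median_rho = stats::median(ps$rho),
    mean_mse = mean(ps$mse), median_mse = stats::median(ps$mse),
    abs_error_proportions = prop_within(pd$abs_error, error_cutoffs),
    rank_delta_proportions = prop_within(pd$rank_delta, rank_cutoffs,
                                         strict = TRUE),
    top_k = top_k, anchor = anchor,
    top_k_abs_error_proportions = prop_within(top$abs_error, error_cutoffs),
    top_k_rank_delta_proportions = prop_within(top$rank_delta, rank_cutoffs,
                                               strict = TRUE))
  structure(list(per_sample = ps, per_drug = pd, summary = summary),
            class = "ranking_report")
}

#' @export
print.ranking_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0(
    "ranking_report: %d samples, %d (sample, drug) pairs\n",
    "  median rho %.3f | mean MSE %.4f\n",
    "  abs error: %s\n  rank delta (strict <): %s\n"),
    s$n_samples, s$n_pairs, s$median_rho, s$mean_mse,
    paste(sprintf("%s=%.2f", names(s$abs_error_proportions),
                  s$abs_error_proportions), collapse = " "),
    paste(sprintf("%s=%.2f", names(s$rank_delta_proportions),
                  s$rank_delta_proportions), collapse = " ")))
  invisible(x)
}

#' Write a ranking report (per-sample and per-drug TSVs plus summary JSON)
#' @param report A `ranking_report`.
#' @param dir Output directory (created if needed).
#' @export
write_ranking_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$per_sample, file.path(dir, "per_sample.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$per_drug, file.path(dir, "per_drug.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
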