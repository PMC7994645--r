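#' Spearman correlation of every drug's D values with a target response
#'
#' Rank correlation (average ranks on ties) between each candidate drug's D
#' values and the target drug's AAC over the paired training cell lines, with
#' a two-sided p-value from the t approximation on `n - 2` degrees of freedom.
#' The target's own D is among the candidates.
#'
#' @param d_matrix A `drug_distance_matrix` (training samples).
#' @param target_aac Named numeric AAC vector over training cell lines.
#' @param min_pairs Minimum paired observations per candidate (default 5).
#' @return Data frame `drug`, `rho`, `p`, `n`; constant-vector candidates are
#'   skipped.
#' @export
spearman_with_response <- function(d_matrix, target_aac, min_pairs = 5L) {
  samples <- intersect(colnames(d_matrix$D), names(target_aac))
  y <- target_aac[samples]
  rows <- lapply(rownames(d_matrix$D), function(d) {
    x <- d_matrix$D[d, samples]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    if (n < min_pairs) return(NULL)
    xs <- x[ok]; ys <- y[ok]
    if (length(unique(xs)) < 2L || length(unique(ys)) < 2L) return(NULL)
    rho <- stats::cor(rank(xs), rank(ys))
    p <- if (abs(rho) >= 1) 0 else {
      tt <- rho * sqrt((n - 2) / (1 - rho^2))
      2 * stats::pt(-abs(tt), df = n - 2)
    }
    data.frame(drug = d, rho = rho, p = p, n = n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(drug = character(0), rho = numeric(0), p = numeric(0),
                      n = integer(0), stringsAsFactors = FALSE)
  out
}

#' Select predictor D features for a target drug
#'
#' Per correlation direction (positive / negative rho): take the significant
#' candidates (`p < alpha`) ranked by `|rho|`; cap at `cap` (30) per
#' direction; if fewer than `floor` (7) are significant, fall back to the top
#' `floor` candidates in that direction by `|rho|` regardless of significance.
#' The union therefore holds between 14 and 60 predictors whenever each
#' direction offers at least 7 candidates. Ties on `|rho|` break
#' lexicographically by drug id for determinism.
#'
#' @param correlations Output of [spearman_with_response()].
#' @param target_drug Target drug id (recorded on the result).
#' @param alpha Significance threshold (default 0.05, raw p).
#' @param cap Maximum predictors per direction (default 30).
#' @param floor_n Minimum predictors per direction (default 7).
#' @return A `predictor_set`: `list(target_drug, predictors, flagged)` where
#'   `predictors` is a data frame `drug`, `rho`, `p`, `direction`.
#' @export
select_predictors <- function(correlations, target_drug = NA_character_,
                              alpha = 0.05, cap = 30L, floor_n = 7L) {
  if (!nrow(correlations)) stop("no predictor candidates for the target drug")
  pick_side <- function(df) {
    df <- df[order(-abs(df$rho), df$drug), , drop = FALSE]
    sig <- df[df$p < alpha, , drop = FALSE]
    if (nrow(sig) > cap) sig[seq_len(cap), , drop = FALSE]
    else if (nrow(sig) < floor_n) df[seq_len(min(floor_n, nrow(df))), , drop = FALSE]
    else sig
  }
  pos <- pick_side(correlations[correlations$rho > 0, , drop = FALSE])
  neg <- pick_side(correlations[correlations$rho < 0, , drop = FALSE])
  flagged <- nrow(pos) < floor_n || nrow(neg) < floor_n
  sel <- rbind(
    if (nrow(pos)) cbind(pos, direction = "+") else NULL,
    if (nrow(neg)) cbind(neg, direction = "-") else NULL)
  if (is.null(sel) || !nrow(sel)) stop("no predictor candidates survived selection")
  rownames(sel) <- NULL
  structure(list(target_drug = target_drug,
                 predictors = sel[, c("drug", "rho", "p", "direction")],
                 cap = cap, floor_n = floor_n, flagged = flagged),
            class = "predictor_set")
}

#' Select predictors for every drug
#'
#' @param d_matrix Training `drug_distance_matrix`.
#' @param responses Scaled [drug_response_table()] (training cell lines).
#' @param drugs Target drugs (default: drugs with computable D).
#' @param ... Passed to [select_predictors()].
#' @return Named list of `predictor_set` objects; drugs whose selection fails
#'   are dropped with a warning.
#' @export
select_all_predictors <- function(d_matrix, responses,
                                  drugs = rownames(d_matrix$D), ...) {
  out <- list()
  for (d in drugs) {
    if (!d %in% rownames(responses$aac)) next
    res <- tryCatch({
      corr <- spearman_with_response(d_matrix, responses$aac[d, ])
      select_predictors(corr, target_drug = d, ...)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("predictor selection failed for '", d, "': ",
              conditionMessage(res))
    } else out[[d]] <- res
  }
  out
}

#' Write predictor sets to JSON
#' @param predictor_sets Named list from [select_all_predictors()].
#' @param path Output JSON.
#' @export
write_predictor_sets <- function(predictor_sets, path) {
  obj <- lapply(predictor_sets, function(ps)
    list(target_drug = ps$target_drug, predictors = ps$predictors,
         flagged = ps$flagged))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
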