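#' Drug-response distance D for one sample
#'
#' For a drug with sensitivity-marker set S and resistance-marker set R, the
#' distance in a sample b is
#' `D = (S_Q2 - R_Q2) + (S_Q3 - R_Q3)`,
#' the difference of the median (Q2) and third-quartile (Q3) statistics of the
#' two marker-value distributions within that sample (type-7 quantiles over
#' the non-missing marker values). D is internally normalized: it compares two
#' marker sets inside one profile, so no reference sample is needed, adding a
#' constant to the whole profile leaves it unchanged, and missing markers are
#' tolerated down to a coverage floor.
#'
#' @param sample_profile Named numeric vector (feature -> value) for one
#'   sample.
#' @param entry An EMDR catalog entry (`sensitivity`, `resistance` sets).
#' @param min_markers Minimum non-missing marker values required on each side
#'   (default 5).
#' @return `list(ok, D, components = c(S_Q2, S_Q3, R_Q2, R_Q3), coverage =
#'   c(sensitivity, resistance), reason)`; `ok = FALSE` with a reason when
#'   coverage is insufficient (never silently zero).
#' @export
compute_distance <- function(sample_profile, entry, min_markers = 5L) {
  sv <- sample_profile[unique(entry$sensitivity)]
  rv <- sample_profile[unique(entry$resistance)]
  sv <- sv[!is.na(sv)]; rv <- rv[!is.na(rv)]
  cov <- c(sensitivity = length(sv), resistance = length(rv))
  if (length(sv) < min_markers || length(rv) < min_markers) {
    return(list(ok = FALSE, D = NA_real_,
                components = c(S_Q2 = NA_real_, S_Q3 = NA_real_,
                               R_Q2 = NA_real_, R_Q3 = NA_real_),
                coverage = cov,
                reason = sprintf("coverage below %d markers (S=%d, R=%d)",
                                 min_markers, length(sv), length(rv))))
  }
  sq <- quartiles_q2_q3(sv)
  rq <- quartiles_q2_q3(rv)
  list(ok = TRUE, D = (sq[1] - rq[1]) + (sq[2] - rq[2]),
       components = c(S_Q2 = sq[1], S_Q3 = sq[2], R_Q2 = rq[1], R_Q3 = rq[2]),
       coverage = cov, reason = NA_character_)
}

#' Compute the drugs-by-samples distance matrix
#'
#' Applies [compute_distance()] to every (drug, sample) combination; entries
#' with insufficient marker coverage stay missing and are reported in the
#' coverage summary.
#'
#' @param omics Cell-line-averaged [omics_matrix()].
#' @param catalog An `emdr_catalog` from [discover_emdr()].
#' @param min_markers Coverage floor per side (default 5).
#' @param verbose Log per-drug computable-sample counts.
#' @return A `drug_distance_matrix`: list with `D` (drugs x samples),
#'   component matrices `S_Q2`, `S_Q3`, `R_Q2`, `R_Q3`, coverage matrices, and
#'   `norm_params` (`NULL` until [fit_minmax()]).
#' @export
distance_matrix <- function(omics, catalog, min_markers = 5L, verbose = FALSE) {
  drugs <- names(catalog)
  samples <- colnames(omics$values)
  mk <- function() matrix(NA_real_, length(drugs), length(samples),
                          dimnames = list(drugs, samples))
  D <- mk(); s2 <- mk(); s3 <- mk(); r2 <- mk(); r3 <- mk()
  cov_s <- mk(); cov_r <- mk()
  for (d in drugs) {
    entry <- catalog[[d]]
    if (!length(entry$sensitivity) || !length(entry$resistance)) next
    for (b in samples) {
      res <- compute_distance(omics$values[, b], entry, min_markers)
      cov_s[d, b] <- res$coverage[["sensitivity"]]
      cov_r[d, b] <- res$coverage[["resistance"]]
      if (res$ok) {
        D[d, b] <- res$D
        s2[d, b] <- res$components[["S_Q2"]]; s3[d, b] <- res$components[["S_Q3"]]
        r2[d, b] <- res$components[["R_Q2"]]; r3[d, b] <- res$components[["R_Q3"]]
      }
    }
    n_ok <- sum(!is.na(D[d, ]))
    if (n_ok == 0L)
      warning("drug '", d, "' has no computable D values; excluded downstream")
    msg(verbose, "D[%s]: %d/%d samples computable", d, n_ok, length(samples))
  }
  structure(list(D = D, S_Q2 = s2, S_Q3 = s3, R_Q2 = r2, R_Q3 = r3,
                 coverage_sensitivity = cov_s, coverage_resistance = cov_r,
                 norm_params = NULL),
            class = "drug_distance_matrix")
}

#' @export
print.drug_distance_matrix <- function(x, ...) {
  cat(sprintf("drug_distance_matrix: %d drugs x %d samples, %.1f%% computable%s\n",
              nrow(x$D), ncol(x$D), 100 * mean(!is.na(x$D)),
              if (!is.null(x$norm_params)) ", normalized 0-1" else ""))
  invisible(x)
}

#' Fit per-drug min-max normalization on a training distance matrix
#'
#' @param train A `drug_distance_matrix` restricted to (or indexed by) the
#'   training samples.
#' @param samples Optional subset of sample ids to fit on.
#' @return Data frame `drug`, `min`, `max`, `degenerate`; degenerate
#'   (constant-D) drugs are flagged for exclusion from modeling.
#' @export
fit_minmax <- function(train, samples = colnames(train$D)) {
  D <- train$D[, samples, drop = FALSE]
  rng <- t(apply(D, 1L, function(x) {
    o <- x[!is.na(x)]
    if (length(unique(o)) < 2L) c(NA_real_, NA_real_) else range(o)
  }))
  out <- data.frame(drug = rownames(D), min = rng[, 1], max = rng[, 2],
                    degenerate = is.na(rng[, 1]), stringsAsFactors = FALSE,
                    row.names = NULL)
  if (any(out$degenerate))
    warning("constant D on training panel for: ",
            paste(out$drug[out$degenerate], collapse = ", "))
  out
}

#' Apply stored min-max normalization to a distance matrix
#'
#' New samples are scaled with the training parameters and clipped to
#' `[0, 1]`, so the normalized features a model sees at prediction time live
#' on the training scale.
#'
#' @param dm A `drug_distance_matrix`.
#' @param norm_params Output of [fit_minmax()].
#' @return A `drug_distance_matrix` whose `D` is normalized (degenerate drugs
#'   become all-`NA`); `norm_params` stored on the object.
#' @export
apply_minmax <- function(dm, norm_params) {
  D <- dm$D
  idx <- match(rownames(D), norm_params$drug)
  if (any(is.na(idx))) stop("norm_params missing drugs present in the matrix")
  lo <- norm_params$min[idx]; hi <- norm_params$max[idx]
  Dn <- (D - lo) / (hi - lo)
  Dn[norm_params$degenerate[idx], ] <- NA_real_
  Dn <- pmin(pmax(Dn, 0), 1)
  out <- dm
  out$D <- Dn
  out$norm_params <- norm_params
  out
}

#' Write a distance matrix (and its coverage counts) to TSV
#' @param dm A `drug_distance_matrix`.
#' @param path D-matrix TSV path; coverage goes to `<path>.coverage.tsv`.
#' @export
write_distance_matrix <- function(dm, path) {
  wr <- function(m, p) utils::write.table(
    data.frame(drug = rownames(m), m, check.names = FALSE),
    p, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  wr(dm$D, path)
  wr(dm$coverage_sensitivity + dm$coverage_resistance,
     paste0(path, ".coverage.tsv"))
  invisible(path)
}
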