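#' Read a GMT gene-set collection
#'
#' Standard tab-delimited GMT: set id, description, then member ids.
#'
#' @param path GMT file path.
#' @return Named list of character member vectors, with a `"descriptions"`
#'   attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, character(1), 1L)
  attr(sets, "descriptions") <-
    stats::setNames(vapply(parts, `[`, character(1), 2L), names(sets))
  sets
}

#' Over-representation of a marker set in gene-set collections
#'
#' For each set: `a` = markers in the set, `b` = marker count, `c` =
#' background features in the set, `d` = background size; the enrichment
#' ratio is `(a/b) / (c/d)` and the p-value is the upper-tail hypergeometric
#' probability of drawing at least `a` set members in `b` draws from the
#' background, BH-adjusted across sets.
#'
#' @param markers Character vector of marker feature ids (must be a subset of
#'   `background`).
#' @param gene_sets Named list of member vectors (see [read_gmt()]); each set
#'   is intersected with the background first.
#' @param background Character vector: all features quantified in the
#'   discovery matrix.
#' @param min_set_size Sets smaller than this after background intersection
#'   are skipped (default 3).
#' @return Data frame of `set_id`, `a`, `b`, `c`, `d`, `ratio`, `p`, `p_adj`;
#'   zero rows when `markers` is empty.
#' @export
enrich_emdr <- function(markers, gene_sets, background, min_set_size = 3L) {
  background <- unique(background)
  if (!length(background)) stop("empty background")
  markers <- unique(markers)
  if (length(setdiff(markers, background)))
    stop("markers must be a subset of the background")
  d <- length(background)
  b <- length(markers)
  rows <- lapply(names(gene_sets), function(sid) {
    set_bg <- intersect(gene_sets[[sid]], background)
    cc <- length(set_bg)
    if (cc < min_set_size) return(NULL)
    a <- length(intersect(markers, set_bg))
    if (b == 0L) return(NULL)
    ratio <- (a / b) / (cc / d)
    p <- stats::phyper(a - 1L, cc, d - cc, b, lower.tail = FALSE)
    data.frame(set_id = sid, a = a, b = b, c = cc, d = d, ratio = ratio,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(set_id = character(0), a = integer(0), b = integer(0),
                      c = integer(0), d = integer(0), ratio = numeric(0),
                      p = numeric(0), p_adj = numeric(0),
                      stringsAsFactors = FALSE))
  out$p_adj <- benjamini_hochberg(out$p)
  out
}

#' Delta enrichment: sensitivity-side minus resistance-side ratios
#'
#' Profiles a drug's mode of action as, per set, the enrichment ratio of its
#' sensitivity markers minus the enrichment ratio of its resistance markers.
#' A side with no computable enrichment contributes ratio 0 (flagged).
#'
#' @param sens_enrichment,res_enrichment Data frames from [enrich_emdr()] for
#'   the two marker sides of one drug.
#' @return Named numeric vector, set id -> delta; attribute
#'   `"missing_side"` names sets seen on one side only.
#' @export
delta_enrichment <- function(sens_enrichment, res_enrichment) {
  sets <- union(sens_enrichment$set_id, res_enrichment$set_id)
  rs <- stats::setNames(rep(0, length(sets)), sets)
  rr <- rs
  rs[sens_enrichment$set_id] <- sens_enrichment$ratio
  rr[res_enrichment$set_id] <- res_enrichment$ratio
  out <- rs - rr
  attr(out, "missing_side") <- c(setdiff(sets, sens_enrichment$set_id),
                                 setdiff(sets, res_enrichment$set_id))
  out
}

#' Enrichment and delta-enrichment for a whole EMDR catalog
#'
#' @param catalog An `emdr_catalog`.
#' @param gene_sets Named list of sets (see [read_gmt()]).
#' @param background Feature universe of the discovery matrix.
#' @param min_set_size See [enrich_emdr()].
#' @return `list(records, delta)`: a long data frame of enrichment records
#'   (columns `drug`, `side`, then [enrich_emdr()] columns) and a drugs x
#'   sets delta-enrichment matrix.
#' @export
enrich_catalog <- function(catalog, gene_sets, background, min_set_size = 3L) {
  records <- list(); deltas <- list()
  for (d in names(catalog)) {
    e <- catalog[[d]]
    se <- enrich_emdr(e$sensitivity, gene_sets, background, min_set_size)
    re <- enrich_emdr(e$resistance, gene_sets, background, min_set_size)
    if (nrow(se)) records[[paste0(d, ".s")]] <-
      cbind(drug = d, side = "sensitivity", se)
    if (nrow(re)) records[[paste0(d, ".r")]] <-
      cbind(drug = d, side = "resistance", re)
    deltas[[d]] <- delta_enrichment(se, re)
  }
  all_sets <- unique(unlist(lapply(deltas, names)))
  delta <- matrix(0, length(deltas), length(all_sets),
                  dimnames = list(names(deltas), all_sets))
  for (d in names(deltas)) delta[d, names(deltas[[d]])] <- deltas[[d]]
  rec <- if (length(records)) do.call(rbind, records) else NULL
  if (!is.null(rec)) rownames(rec) <- NULL
  list(records = rec, delta = delta)
}

#' Drug-drug similarity from delta-enrichment profiles
#'
#' Pairwise Pearson correlation of the drugs' delta-enrichment vectors
#' (pairwise-complete); the off-diagonal correlation values are rescaled so
#' that their distribution has median 0 and standard deviation 1, and each
#' pair's p-value is a one-sample t-test of the full scaled-score
#' distribution against that pair's score.
#'
#' @param delta_matrix Drugs x sets matrix from [enrich_catalog()].
#' @return A `similarity_matrix`: `list(r, score, p)` of symmetric drugs x
#'   drugs matrices (diagonal excluded from the scaling distribution; pairs
#'   involving constant profiles are `NA`).
#' @export
similarity_scores <- function(delta_matrix) {
  if (nrow(delta_matrix) < 3L || ncol(delta_matrix) < 3L)
    stop("need at least 3 drugs and 3 sets")
  r <- suppressWarnings(
    stats::cor(t(delta_matrix), use = "pairwise.complete.obs",
               method = "pearson"))
  off <- r[upper.tri(r)]
  off <- off[!is.na(off)]
  if (length(off) < 3L) stop("too few computable drug pairs")
  ctr <- stats::median(off); scl <- stats::sd(off)
  if (scl == 0) stop("degenerate similarity distribution (zero spread)")
  score <- (r - ctr) / scl
  scaled_off <- (off - ctr) / scl
  p <- matrix(NA_real_, nrow(r), ncol(r), dimnames = dimnames(r))
  for (i in seq_len(nrow(r))) for (j in seq_len(ncol(r))) {
    if (i == j || is.na(score[i, j])) next
    p[i, j] <- stats::t.test(scaled_off, mu = score[i, j])$p.value
  }
  structure(list(r = r, score = score, p = p), class = "similarity_matrix")
}

#' Write enrichment outputs (records TSV, similarity matrices)
#' @param enrichment Output of [enrich_catalog()].
#' @param similarity Optional output of [similarity_scores()].
#' @param dir Output directory.
#' @export
write_enrichment <- function(enrichment, similarity = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(enrichment$records))
    utils::write.table(enrichment$records, file.path(dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(drug = rownames(enrichment$delta), enrichment$delta,
               check.names = FALSE),
    file.path(dir, "delta_enrichment.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(similarity)) {
    utils::write.table(
      data.frame(drug = rownames(similarity$score), similarity$score,
                 check.names = FALSE),
      file.path(dir, "similarity.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    lt <- which(lower.tri(similarity$r), arr.ind = TRUE)
    pairs <- data.frame(
      drug_a = rownames(similarity$r)[lt[, 1]],
      drug_b = colnames(similarity$r)[lt[, 2]],
      r = similarity$r[lt], score = similarity$score[lt],
      p = similarity$p[lt], stringsAsFactors = FALSE)
    utils::write.table(pairs, file.path(dir, "similarity_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
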