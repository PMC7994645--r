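#' Construct an omics abundance matrix
#'
#' The central input container: a real-valued features-by-samples matrix of
#' (phospho)protein or transcript abundances, with an optional map from
#' replicate samples to cell lines. Missing entries are `NA` and are never
#' imputed by this package; downstream operations handle them explicitly.
#'
#' @param values Numeric matrix, features in rows (unique rownames) and samples
#'   in columns (colnames).
#' @param layer One of `"phospho"`, `"proteome"`, `"rnaseq"`.
#' @param replicate_map Optional named character vector mapping every sample id
#'   to a cell-line id. Defaults to the identity map (each sample its own line).
#' @param normalized Logical; `TRUE` once features have been centered/scaled.
#' @return An object of class `omics_matrix`.
#' @export
omics_matrix <- function(values, layer = c("phospho", "proteome", "rnaseq"),
                         replicate_map = NULL, normalized = FALSE) {
  layer <- match.arg(layer)
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have feature rownames and sample colnames")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup))
    stop("duplicate feature ids: ", paste(unique(dup), collapse = ", "))
  if (is.null(replicate_map)) {
    replicate_map <- stats::setNames(colnames(values), colnames(values))
  }
  missing_map <- setdiff(colnames(values), names(replicate_map))
  if (length(missing_map))
    stop("replicate_map does not cover samples: ",
         paste(missing_map, collapse = ", "))
  structure(
    list(values = values, layer = layer,
         replicate_map = replicate_map[colnames(values)],
         normalized = isTRUE(normalized),
         zero_variance_features = character(0)),
    class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix [%s]: %d features x %d samples (%d cell lines), %.1f%% missing%s\n",
              x$layer, nrow(x$values), ncol(x$values),
              length(unique(x$replicate_map)),
              100 * mean(is.na(x$values)),
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Read an omics matrix from TSV
#'
#' Expects a UTF-8 tab-delimited file whose first column holds feature ids and
#' whose remaining columns (named in the header) hold per-sample abundances.
#' Empty cells become missing values; any other non-numeric cell is an error
#' reporting its location.
#'
#' @param path TSV file path.
#' @param layer Omics layer, see [omics_matrix()].
#' @param replicate_map_path Optional two-column TSV (sample_id, cell_line_id).
#' @param verbose Log dimensions and missingness.
#' @return An [omics_matrix()].
#' @export
load_omics_matrix <- function(path, layer = "phospho",
                              replicate_map_path = NULL, verbose = FALSE) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", na.strings = NULL)
  if (ncol(raw) < 2L) stop("expected a feature-id column plus >=1 sample column")
  feat <- raw[[1L]]
  dup <- unique(feat[duplicated(feat)])
  if (length(dup))
    stop("duplicate feature ids: ", paste(dup, collapse = ", "))
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) & !(vals == "" | vals == "NA"), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric cell at feature '%s', sample '%s': '%s'",
                 feat[bad[1, 1]], colnames(vals)[bad[1, 2]],
                 vals[bad[1, 1], bad[1, 2]]))
  dimnames(num) <- list(feat, colnames(vals))
  rmap <- NULL
  if (!is.null(replicate_map_path)) {
    mp <- utils::read.delim(replicate_map_path, header = TRUE, sep = "\t",
                            colClasses = "character")
    rmap <- stats::setNames(mp[[2L]], mp[[1L]])
  }
  m <- omics_matrix(num, layer = layer, replicate_map = rmap)
  msg(verbose, "loaded %d features x %d samples from %s (%.2f%% missing)",
      nrow(num), ncol(num), path, 100 * mean(is.na(num)))
  m
}

#' Write an omics matrix to TSV
#'
#' Mirrors [load_omics_matrix()]: a round trip reproduces finite values
#' bit-exactly (values are printed with full precision).
#'
#' @param m An [omics_matrix()].
#' @param path Output file.
#' @export
write_omics_matrix <- function(m, path) {
  df <- data.frame(feature = rownames(m$values),
                   m$values, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Construct a drug-response table
#'
#' AAC (area above the dose-response curve) values, drugs in rows and cell
#' lines in columns. Values live on `[0, 1]` after [scale_aac()] (0 = no
#' effect, 1 = maximum cell killing); missing entries are allowed.
#'
#' @param aac Numeric matrix with drug rownames and cell-line colnames.
#' @param scaled Logical; `TRUE` once per-cell-line min-max scaled.
#' @return An object of class `drug_response_table`.
#' @export
drug_response_table <- function(aac, scaled = FALSE) {
  stopifnot(is.matrix(aac), is.numeric(aac))
  if (is.null(rownames(aac)) || is.null(colnames(aac)))
    stop("'aac' must have drug rownames and cell-line colnames")
  if (any(duplicated(rownames(aac)))) stop("duplicate drug ids")
  if (any(!is.finite(aac) & !is.na(aac))) stop("non-finite AAC values present")
  structure(list(aac = aac, scaled = isTRUE(scaled)),
            class = "drug_response_table")
}

#' @export
print.drug_response_table <- function(x, ...) {
  cat(sprintf("drug_response_table: %d drugs x %d cell lines%s\n",
              nrow(x$aac), ncol(x$aac), if (x$scaled) " (scaled 0-1)" else ""))
  invisible(x)
}

#' Read a drug-response TSV (first column drug id, columns = cell lines)
#' @param path TSV file path.
#' @param scaled Whether the file already holds scaled values.
#' @return A [drug_response_table()].
#' @export
load_drug_response_table <- function(path, scaled = FALSE) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  aac <- as.matrix(raw[, -1L, drop = FALSE])
  rownames(aac) <- as.character(raw[[1L]])
  storage.mode(aac) <- "double"
  drug_response_table(aac, scaled = scaled)
}

#' Write a drug-response table to TSV
#' @param tbl A [drug_response_table()].
#' @param path Output file.
#' @export
write_drug_response_table <- function(tbl, path) {
  df <- data.frame(drug = rownames(tbl$aac), tbl$aac,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Scale AAC values to span 0-1 within each cell line
#'
#' Min-max scales each cell line's observed responses across its drugs, so that
#' 0 means no effect and 1 the line's maximum cell killing; this normalizes for
#' assay conditions before any cross-line comparison. The alternative per-drug
#' axis is exposed for sensitivity analysis.
#'
#' @param raw A [drug_response_table()].
#' @param axis `"cell_line"` (default) or `"drug"`.
#' @return A scaled [drug_response_table()]; idempotent on already-spanned
#'   columns.
#' @export
scale_aac <- function(raw, axis = c("cell_line", "drug")) {
  axis <- match.arg(axis)
  aac <- raw$aac
  scale_vec <- function(x, who) {
    obs <- x[!is.na(x)]
    if (length(unique(obs)) < 2L)
      stop("degenerate AAC scaling for ", who,
           ": fewer than 2 distinct observed values")
    (x - min(obs)) / (max(obs) - min(obs))
  }
  if (axis == "cell_line") {
    for (j in seq_len(ncol(aac)))
      aac[, j] <- scale_vec(aac[, j], paste0("cell line '", colnames(aac)[j], "'"))
  } else {
    for (i in seq_len(nrow(aac)))
      aac[i, ] <- scale_vec(aac[i, ], paste0("drug '", rownames(aac)[i], "'"))
  }
  drug_response_table(aac, scaled = TRUE)
}

#' Filter drugs by across-cell-line interquartile range
#'
#' Drops drugs whose response spread (Q3 - Q1, type-7 quantiles over observed
#' cell lines) is not strictly greater than `threshold` AAC units; drugs with
#' near-constant responses carry no signal for sensitive/resistant contrasts.
#'
#' @param table A scaled [drug_response_table()].
#' @param threshold IQR cutoff in AAC units (default 0.15; strict `>`).
#' @return The filtered table, with attribute `"iqr_report"`: a data frame of
#'   drug, iqr and kept flag.
#' @export
filter_drugs_by_iqr <- function(table, threshold = 0.15) {
  if (!table$scaled) stop("filter_drugs_by_iqr expects a scaled table")
  iqr <- apply(table$aac, 1L, function(x) {
    q <- stats::quantile(x, c(0.25, 0.75), na.rm = TRUE, type = 7, names = FALSE)
    q[2] - q[1]
  })
  keep <- iqr > threshold
  if (!any(keep)) warning("no drugs pass the IQR filter")
  out <- drug_response_table(table$aac[keep, , drop = FALSE], scaled = TRUE)
  attr(out, "iqr_report") <- data.frame(
    drug = rownames(table$aac), iqr = unname(iqr), kept = unname(keep),
    stringsAsFactors = FALSE)
  out
}

#' Center and scale features (z-score per feature)
#'
#' Per feature: subtract the mean and divide by the sd (n-1 denominator) over
#' non-missing entries. Zero-variance features are set to 0 and recorded in
#' `zero_variance_features`. Optionally apply `log2(x + pseudocount)` first for
#' raw-intensity layers.
#'
#' @param m An [omics_matrix()].
#' @param log2_transform Apply a log2 pre-transform (default `FALSE`).
#' @param pseudocount Added before log2 when transforming.
#' @return A normalized [omics_matrix()]; applying twice is a fixed point to
#'   within 1e-9.
#' @export
center_scale_features <- function(m, log2_transform = FALSE, pseudocount = 1) {
  v <- m$values
  if (log2_transform) v <- log2(v + pseudocount)
  mu <- rowMeans(v, na.rm = TRUE)
  sdv <- apply(v, 1L, stats::sd, na.rm = TRUE)
  zero <- is.na(sdv) | sdv < .Machine$double.eps^0.5
  v <- (v - mu) / ifelse(zero, 1, sdv)
  v[zero, ] <- ifelse(is.na(m$values[zero, , drop = FALSE]), NA_real_, 0)
  out <- omics_matrix(v, layer = m$layer, replicate_map = m$replicate_map,
                      normalized = TRUE)
  out$zero_variance_features <- rownames(m$values)[zero]
  out
}

#' Average replicate samples into one column per cell line
#'
#' Collapses replicate measurements using the per-feature mean over non-missing
#' replicates; an entry stays missing only if it is missing in every replicate.
#'
#' @param m An [omics_matrix()] whose `replicate_map` names the cell line of
#'   each sample.
#' @return An [omics_matrix()] with one column per cell line (identity
#'   replicate map).
#' @export
average_replicates <- function(m) {
  lines <- unique(unname(m$replicate_map))
  if (!length(lines)) stop("empty replicate map")
  avg <- vapply(lines, function(cl) {
    cols <- names(m$replicate_map)[m$replicate_map == cl]
    if (!length(cols)) stop("cell line with zero samples: ", cl)
    sub <- m$values[, cols, drop = FALSE]
    r <- rowMeans(sub, na.rm = TRUE)
    r[!is.finite(r)] <- NA_real_
    r
  }, numeric(nrow(m$values)))
  dimnames(avg) <- list(rownames(m$values), lines)
  out <- omics_matrix(avg, layer = m$layer, normalized = m$normalized)
  out$zero_variance_features <- m$zero_variance_features
  out
}
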