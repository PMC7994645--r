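#' Specification of a synthetic cell-line panel
#'
#' Describes a panel with known ground truth: per drug, a latent sensitivity
#' in `[0, 1]` (equal to its AAC), planted sensitivity markers whose abundance
#' rises linearly with that latent, planted resistance markers that fall with
#' it, and null features of pure Gaussian noise. Drugs come in clusters that
#' share a cluster-level latent factor, which induces correlated responses —
#' and therefore correlated markers and D values — within a cluster, the
#' structure the predictor-selection stage exploits. Replicate measurements
#' add independent noise; entries are masked missing at a fixed rate.
#'
#' @param n_cell_lines Number of cell lines.
#' @param n_replicates Replicate samples per cell line (default 3).
#' @param n_features Total features (planted + null).
#' @param n_drugs Number of drugs.
#' @param n_clusters Number of drug clusters (drugs split evenly).
#' @param n_sens_markers,n_res_markers Planted markers per drug and direction.
#' @param effect_size Marker slope Delta, in units of the noise sd.
#' @param noise_sd Replicate noise standard deviation.
#' @param missing_rate Fraction of entries masked missing, in `[0, 1)`.
#' @param cluster_weight Weight of the shared cluster latent in a drug's
#'   sensitivity (default 0.5).
#' @param seed Integer seed.
#' @return A `panel_spec` list.
#' @export
panel_spec <- function(n_cell_lines, n_replicates = 3L, n_features,
                       n_drugs, n_clusters = 1L,
                       n_sens_markers = 20L, n_res_markers = 20L,
                       effect_size = 2, noise_sd = 1, missing_rate = 0.05,
                       cluster_weight = 0.5, seed = 1L) {
  spec <- list(n_cell_lines = as.integer(n_cell_lines),
               n_replicates = as.integer(n_replicates),
               n_features = as.integer(n_features),
               n_drugs = as.integer(n_drugs),
               n_clusters = as.integer(n_clusters),
               n_sens_markers = as.integer(n_sens_markers),
               n_res_markers = as.integer(n_res_markers),
               effect_size = effect_size, noise_sd = noise_sd,
               missing_rate = missing_rate,
               cluster_weight = cluster_weight, seed = as.integer(seed))
  with(spec, {
    stopifnot(n_cell_lines > 0, n_replicates > 0, n_features > 0, n_drugs > 0,
              n_clusters > 0, n_sens_markers >= 0, n_res_markers >= 0,
              effect_size >= 0, noise_sd > 0,
              missing_rate >= 0, missing_rate < 1)
  })
  structure(spec, class = "panel_spec")
}

#' Reference panel settings used throughout the test suite
#'
#' 24 cell lines x 3 replicates, 1000 features, 24 drugs in 6 clusters,
#' 20 sensitivity + 20 resistance markers per drug, effect size Delta = 2
#' noise sd, noise sd 1, 5% missingness, seed 17.
#'
#' @return A [panel_spec()].
#' @export
reference_settings <- function() {
  panel_spec(n_cell_lines = 24L, n_replicates = 3L, n_features = 1000L,
             n_drugs = 24L, n_clusters = 6L,
             n_sens_markers = 20L, n_res_markers = 20L,
             effect_size = 2, noise_sd = 1, missing_rate = 0.05, seed = 17L)
}

#' Generate a synthetic panel with planted ground truth
#'
#' Per drug `d` and cell line `c`: a latent sensitivity `s_dc` is formed from
#' a cluster-shared and an independent uniform component and rank-transformed
#' per drug to an exact uniform grid on `[0, 1]`; the AAC is `s_dc`. Planted
#' sensitivity markers have mean abundance `Delta * (s_dc - 0.5)`, resistance
#' markers the negated slope, null features mean 0; every replicate adds
#' `N(0, noise_sd^2)` noise and entries are masked missing at
#' `missing_rate`. Deterministic given the spec seed.
#'
#' @param spec A [panel_spec()].
#' @return `list(omics, responses, truth)` where `omics` is an
#'   [omics_matrix()] (replicates, raw scale), `responses` a
#'   [drug_response_table()] (`scaled = FALSE`; values already in `[0, 1]`)
#'   and `truth` the ground truth (per-drug planted marker ids and direction,
#'   cluster membership, true AAC).
#' @export
generate_panel <- function(spec) {
  set.seed(spec$seed)
  nL <- spec$n_cell_lines; nR <- spec$n_replicates
  nD <- spec$n_drugs; nF <- spec$n_features; nK <- spec$n_clusters
  demand <- nD * (spec$n_sens_markers + spec$n_res_markers)
  if (demand > nF)
    stop(sprintf("marker demand (%d) exceeds n_features (%d)", demand, nF))

  lines <- sprintf("cell%02d", seq_len(nL))
  drugs <- sprintf("drug%02d", seq_len(nD))
  feats <- sprintf("f%04d", seq_len(nF))
  cluster_of <- rep(seq_len(nK), length.out = nD)

  # latent sensitivities: cluster factor + independent part, then per-drug
  # rank transform to a uniform grid (keeps the marginal uniform while
  # preserving within-cluster correlation)
  u <- matrix(stats::runif(nK * nL), nK, nL)           # cluster latents
  s <- matrix(NA_real_, nD, nL, dimnames = list(drugs, lines))
  for (di in seq_len(nD)) {
    z <- spec$cluster_weight * u[cluster_of[di], ] +
      (1 - spec$cluster_weight) * stats::runif(nL)
    s[di, ] <- (rank(z, ties.method = "first") - 0.5) / nL
  }

  # disjoint per-drug marker blocks; the remainder stays null
  pool <- feats
  take <- function(n) { out <- pool[seq_len(n)]; pool <<- pool[-seq_len(n)]; out }
  truth_drugs <- list()
  signal <- matrix(0, nF, nL, dimnames = list(feats, lines))
  for (di in seq_len(nD)) {
    sens <- take(spec$n_sens_markers); res <- take(spec$n_res_markers)
    slope <- spec$effect_size * (s[di, ] - 0.5)
    if (length(sens))
      signal[sens, ] <- matrix(slope, length(sens), nL, byrow = TRUE)
    if (length(res))
      signal[res, ] <- matrix(-slope, length(res), nL, byrow = TRUE)
    truth_drugs[[drugs[di]]] <- list(
      sensitivity = sens, resistance = res, cluster = cluster_of[di],
      aac = stats::setNames(s[di, ], lines))
  }

  # replicate measurements with noise and missingness
  sample_ids <- as.vector(outer(lines, seq_len(nR),
                                function(l, r) sprintf("%s_rep%d", l, r)))
  rep_map <- stats::setNames(rep(lines, times = nR), sample_ids)
  values <- signal[, rep_map[sample_ids], drop = FALSE] +
    matrix(stats::rnorm(nF * length(sample_ids), sd = spec$noise_sd),
           nF, length(sample_ids))
  colnames(values) <- sample_ids
  if (spec$missing_rate > 0) {
    mask <- matrix(stats::runif(length(values)) < spec$missing_rate,
                   nrow(values), ncol(values))
    values[mask] <- NA_real_
  }

  omics <- omics_matrix(values, layer = "phospho", replicate_map = rep_map)
  responses <- drug_response_table(s, scaled = FALSE)
  truth <- structure(list(drugs = truth_drugs,
                          cluster_of = stats::setNames(cluster_of, drugs),
                          spec = spec),
                     class = "panel_truth")
  list(omics = omics, responses = responses, truth = truth)
}

#' Write a generated panel (omics TSV, replicate map, responses, truth JSON)
#' @param panel Output of [generate_panel()].
#' @param dir Output directory.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_omics_matrix(panel$omics, file.path(dir, "omics.tsv"))
  utils::write.table(
    data.frame(sample_id = names(panel$omics$replicate_map),
               cell_line_id = unname(panel$omics$replicate_map)),
    file.path(dir, "replicate_map.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  write_drug_response_table(panel$responses, file.path(dir, "responses.tsv"))
  jsonlite::write_json(
    list(spec = unclass(panel$truth$spec),
         cluster_of = as.list(panel$truth$cluster_of),
         drugs = lapply(panel$truth$drugs, function(e)
           list(sensitivity = e$sensitivity, resistance = e$resistance,
                cluster = e$cluster, aac = as.list(e$aac)))),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
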