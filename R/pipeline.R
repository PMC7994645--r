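#' Default run configuration
#'
#' All tunable parameters of the pipeline with their defaults: EMDR discovery
#' thresholds (fold 0.8, p 0.05, consistency 0.8, k = 10 folds), predictor
#' selection (cap 30, floor 7, alpha 0.05), D coverage floor (5 markers per
#' side), training partition ratio (0.8), CV protocol (10-fold x 3 repeats),
#' the algorithm roster, and the evaluation top-k (20). Round-trips
#' losslessly through YAML.
#'
#' @param omics,responses,gmt,out Optional file paths (omics TSV, response
#'   TSV, GMT collection, output directory).
#' @param seed Master seed.
#' @param ... Overrides for any default parameter.
#' @return A `run_config` list.
#' @export
run_config <- function(omics = NULL, responses = NULL, gmt = NULL,
                       out = NULL, seed = 1L, ...) {
  cfg <- list(
    paths = list(omics = omics, responses = responses, gmt = gmt, out = out),
    seed = as.integer(seed),
    scale_axis = "cell_line",
    iqr_threshold = 0.15,
    log2_transform = FALSE,
    emdr = emdr_params(),
    min_markers = 5L,
    selection = list(alpha = 0.05, cap = 30L, floor_n = 7L),
    partition_ratio = 0.8,
    cv = list(k = 10L, repeats = 3L),
    roster = names(algorithm_registry()),
    top_k = 20L,
    verbose = FALSE)
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  stopifnot(cfg$iqr_threshold >= 0, cfg$partition_ratio > 0,
            cfg$partition_ratio < 1, cfg$min_markers >= 1,
            cfg$selection$floor_n >= 1,
            cfg$selection$cap >= cfg$selection$floor_n)
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as YAML
#' @param path YAML file.
#' @return For `read_run_config`, a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- run_config()
  for (nm in names(raw)) cfg[[nm]] <- raw[[nm]]
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' @rdname read_run_config
#' @param cfg A `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Guard against validation-sample leakage
#'
#' Asserts that no validation cell line appears in the sample sets used for
#' EMDR discovery, predictor selection or D normalization. Aborts the run on
#' violation.
#'
#' @param validation Validation cell-line ids.
#' @param used Named list of character vectors: stage name -> cell lines the
#'   stage consumed.
#' @return Invisibly `TRUE` when clean.
#' @export
assert_no_leakage <- function(validation, used) {
  for (stage in names(used)) {
    leak <- intersect(validation, used[[stage]])
    if (length(leak))
      stop("leakage guard: validation cell line(s) ",
           paste(leak, collapse = ", "), " used in stage '", stage, "'")
  }
  invisible(TRUE)
}

#' Run the full pipeline on a panel
#'
#' Executes: AAC scaling and IQR drug filtering; replicate averaging and
#' feature centering/scaling; cell-line partition (training fraction
#' `partition_ratio`); EMDR discovery on training lines only; D computation
#' for all samples; per-drug min-max normalization fitted on training lines;
#' Spearman predictor selection on training lines; roster training; held-out
#' prediction and ranking evaluation; optional marker-set enrichment when
#' gene sets are supplied. Writes stage outputs and a manifest when
#' `cfg$paths$out` is set.
#'
#' @param cfg A [run_config()].
#' @param panel Optional pre-built panel `list(omics, responses)` (e.g. from
#'   [generate_panel()]); otherwise loaded from `cfg$paths`.
#' @param gene_sets Optional named list of sets for enrichment.
#' @param algorithm Algorithm used for the held-out evaluation (default
#'   `"random_forest"`).
#' @return A `pipeline_result` list with every intermediate artifact and a
#'   `manifest` (config hash, seeds, partition, stage summaries).
#' @export
run_pipeline <- function(cfg, panel = NULL, gene_sets = NULL,
                         algorithm = "random_forest") {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (is.null(panel)) {
    panel <- stage("load", list(
      omics = load_omics_matrix(cfg$paths$omics),
      responses = load_drug_response_table(cfg$paths$responses)))
  }
  if (is.null(gene_sets) && !is.null(cfg$paths$gmt))
    gene_sets <- stage("load-gmt", read_gmt(cfg$paths$gmt))

  responses <- stage("scale-aac", {
    r <- panel$responses
    if (!r$scaled) r <- scale_aac(r, axis = cfg$scale_axis)
    filter_drugs_by_iqr(r, cfg$iqr_threshold)
  })
  omics <- stage("normalize", {
    m <- average_replicates(panel$omics)
    center_scale_features(m, log2_transform = cfg$log2_transform)
  })

  lines <- intersect(colnames(omics$values), colnames(responses$aac))
  part <- stage("partition",
    partition_cell_lines(lines, responses, ratio = cfg$partition_ratio,
                         seed = derive_seed(cfg$seed, "partition")))
  omics_train <- stage("subset-train", {
    keep <- part$train
    m <- omics; m$values <- m$values[, keep, drop = FALSE]
    m$replicate_map <- m$replicate_map[keep]; m
  })
  resp_train <- stage("subset-train-resp", {
    r <- responses; r$aac <- r$aac[, part$train, drop = FALSE]; r
  })
  assert_no_leakage(part$validation,
                    list(`emdr-discovery` = colnames(omics_train$values)))

  catalog <- stage("discover-emdr",
    discover_emdr(omics_train, resp_train, params = cfg$emdr,
                  seed = derive_seed(cfg$seed, "emdr"),
                  verbose = cfg$verbose))
  dmat <- stage("distance",
    distance_matrix(omics, catalog, min_markers = cfg$min_markers,
                    verbose = cfg$verbose))
  norm_params <- stage("fit-minmax", fit_minmax(dmat, samples = part$train))
  dnorm <- stage("apply-minmax", apply_minmax(dmat, norm_params))
  dnorm_train <- stage("subset-dnorm", {
    d <- dnorm; for (nm in c("D", "S_Q2", "S_Q3", "R_Q2", "R_Q3",
                             "coverage_sensitivity", "coverage_resistance"))
      d[[nm]] <- d[[nm]][, part$train, drop = FALSE]
    d
  })
  assert_no_leakage(part$validation,
                    list(`predictor-selection` = colnames(dnorm_train$D),
                         `minmax-fit` = part$train))
  predictor_sets <- stage("select",
    select_all_predictors(dnorm_train, resp_train,
                          alpha = cfg$selection$alpha,
                          cap = cfg$selection$cap,
                          floor_n = cfg$selection$floor_n))
  ensemble <- stage("train",
    train_ensemble(dnorm, responses, predictor_sets, part$train,
                   roster = cfg$roster, cv_k = cfg$cv$k,
                   cv_repeats = cfg$cv$repeats,
                   seed = derive_seed(cfg$seed, "train"),
                   verbose = cfg$verbose))
  dmat_val <- stage("subset-val", {
    d <- dmat; for (nm in c("D", "S_Q2", "S_Q3", "R_Q2", "R_Q3",
                            "coverage_sensitivity", "coverage_resistance"))
      d[[nm]] <- d[[nm]][, part$validation, drop = FALSE]
    d
  })
  predictions <- stage("predict",
    predict_responses(ensemble, dmat_val, algorithm = algorithm))
  report <- stage("evaluate",
    evaluate_predictions(predictions, responses, top_k = cfg$top_k))

  enrichment <- NULL; similarity <- NULL
  if (!is.null(gene_sets)) {
    enrichment <- stage("enrich",
      enrich_catalog(catalog, gene_sets, rownames(omics$values)))
    similarity <- stage("similarity", tryCatch(
      similarity_scores(enrichment$delta), error = function(e) NULL))
  }

  stage_samples <- list(
    `emdr-discovery` = colnames(omics_train$values),
    `predictor-selection` = colnames(dnorm_train$D),
    `minmax-fit` = part$train,
    `model-training` = unique(unlist(lapply(ensemble$drugs, function(e)
      e$train_lines))))
  assert_no_leakage(part$validation, stage_samples)

  manifest <- list(
    package_version = as.character(utils::packageVersion("emdrank")),
    config_hash = config_hash(unclass(cfg)),
    seed = cfg$seed,
    partition = part,
    stage_samples = stage_samples,
    roster = ensemble$roster,
    roster_standins = list(rule_committee = "gradient-boosted trees",
                           bayes_glm = "ridge GLM",
                           mlp_deep = "two-hidden-layer perceptron"),
    n_drugs = nrow(responses$aac),
    n_drugs_modeled = length(ensemble$drugs),
    evaluation_algorithm = algorithm,
    summary = report$summary)

  result <- structure(
    list(config = cfg, responses = responses, omics = omics,
         partition = part, catalog = catalog, distances = dmat,
         norm_params = norm_params, distances_norm = dnorm,
         predictor_sets = predictor_sets, ensemble = ensemble,
         predictions = predictions, report = report,
         enrichment = enrichment, similarity = similarity,
         manifest = manifest),
    class = "pipeline_result")

  if (!is.null(cfg$paths$out)) {
    out <- cfg$paths$out
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    write_emdr_catalog(catalog, file.path(out, "catalog.json"))
    write_distance_matrix(dmat, file.path(out, "D.tsv"))
    write_predictor_sets(predictor_sets, file.path(out, "predictors.json"))
    utils::write.table(
      data.frame(drug = rownames(predictions), predictions,
                 check.names = FALSE),
      file.path(out, "predictions.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE, na = "")
    write_ranking_report(report, file.path(out, "report"))
    if (!is.null(enrichment))
      write_enrichment(enrichment, similarity, file.path(out, "enrichment"))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  result
}
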