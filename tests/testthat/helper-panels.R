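# Shared fixtures, built once per test run and memoised across test files.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

ref_panel <- function() memo("ref_panel", function() {
  generate_panel(reference_settings())
})

# normalized inputs for the reference panel (full 24 lines)
ref_inputs <- function() memo("ref_inputs", function() {
  panel <- ref_panel()
  list(
    omics = center_scale_features(average_replicates(panel$omics)),
    responses = filter_drugs_by_iqr(scale_aac(panel$responses)),
    truth = panel$truth)
})

# full-panel EMDR catalog at reference settings (used by recovery checks)
ref_catalog <- function() memo("ref_catalog", function() {
  inp <- ref_inputs()
  discover_emdr(inp$omics, inp$responses, seed = 17L)
})

# end-to-end pipeline at reference settings, random-forest roster
ref_pipeline <- function() memo("ref_pipeline", function() {
  run_pipeline(run_config(seed = 17L, roster = "random_forest"),
               panel = ref_panel())
})

# small fast panel for unit tests: 16 lines, 2 drugs, 120 features
small_panel <- function() memo("small_panel", function() {
  generate_panel(panel_spec(
    n_cell_lines = 16L, n_replicates = 2L, n_features = 120L, n_drugs = 2L,
    n_clusters = 1L, n_sens_markers = 8L, n_res_markers = 8L,
    effect_size = 2, noise_sd = 1, missing_rate = 0.02, seed = 7L))
})

marker_recovery <- function(entry, truth_entry) {
  tp <- length(intersect(entry$sensitivity, truth_entry$sensitivity)) +
    length(intersect(entry$resistance, truth_entry$resistance))
  called <- length(entry$sensitivity) + length(entry$resistance)
  planted <- length(truth_entry$sensitivity) + length(truth_entry$resistance)
  c(tp = tp, called = called, planted = planted)
}
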