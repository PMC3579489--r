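# Small ground-truth scenes for unit tests, plus cached full-scale runs
# shared between the slower integration tests.

tiny_components <- function(n_samples, n_spots = 2, contam = FALSE) {
  comps <- list(list(spatial_role = "background",
                     present_in = seq_len(n_samples),
                     amplitude = 100, spot_radius_fraction = 0.32))
  subsets <- list(seq_len(n_samples),
                  seq_len(max(1, floor(n_samples / 2))),
                  n_samples)
  for (j in seq_len(n_spots)) {
    comps[[length(comps) + 1]] <-
      list(spatial_role = "spot", present_in = subsets[[(j - 1) %% 3 + 1]],
           amplitude = 150, spot_radius_fraction = 0.32)
  }
  if (contam) {
    comps[[length(comps) + 1]] <-
      list(spatial_role = "contamination", present_in = 1,
           amplitude = 120, spot_radius_fraction = 0.26)
  }
  comps
}

tiny_spec <- function(n_samples = 2, height = 16, width = 16,
                      n_channels = 12, n_spots = 2, contam = FALSE,
                      noise = "none", seed = 1) {
  phantom_spec(n_samples = n_samples, height = height, width = width,
               n_channels = n_channels,
               components = tiny_components(n_samples, n_spots, contam),
               noise = noise, seed = seed)
}

tiny_truth <- function(...) generate_phantom(tiny_spec(...))

tiny_matrix <- function(...) {
  truth <- tiny_truth(...)
  consolidate(truth$cubes, truth$peaklist)
}

# --- cached full-scale fixtures (built once per test session) ---------

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# the reference multi-sample scene: 8 samples, 64 x 64 px, 30 channels,
# 5 components (background + 3 spot chemistries + 1 contamination)
study_truth <- function(noise = "none") {
  cached(paste0("truth_", noise), function()
    generate_phantom(phantom_spec(seed = 42, noise = noise)))
}

study_matrix <- function(noise = "none") {
  cached(paste0("cm_", noise), function() {
    truth <- study_truth(noise)
    consolidate(truth$cubes, truth$peaklist)
  })
}

study_consensus <- function(noise = "none") {
  cached(paste0("consensus_", noise), function()
    run_consensus(study_matrix(noise), k = 5, n_repeats = 10,
                  master_seed = 42))
}

# cosine-matched recovery of the final model against ground truth
study_recovery <- function(noise = "none") {
  cached(paste0("recovery_", noise), function() {
    res <- study_consensus(noise)
    truth <- study_truth(noise)
    match_components(res$final_model$loadings, truth$true_loadings)
  })
}
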