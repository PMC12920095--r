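# Shared fixtures: cohort features and the mesh registration are expensive,
# so they are computed once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

shared_registration <- function() {
  cached("registration", calibrate_registration(roi_scan_config()))
}

# cohort features for a class over fixed seeds (study condition: seeds 1..n)
cohort_features_cached <- function(class_label, n = 30) {
  key <- sprintf("cohort_%s_%d", class_label, n)
  cached(key, simulate_cohort_features(class_label, seeds = seq_len(n),
                                       registration = shared_registration()))
}

# one small simulated ROI per class, shared across test files
shared_sim <- function(class_label, seed = 1L) {
  key <- sprintf("sim_%s_%d", class_label, seed)
  cached(key, simulate_roi(class_label, seed = seed))
}
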