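# Shared expensive fixtures, built once per test run and cached. All cohorts
# use the generator's default physiology; the "null" cohort disables every
# event-locked response so labels are independent of the signals.

.oxi_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.oxi_cache[[key]])) .oxi_cache[[key]] <- builder()
  .oxi_cache[[key]]
}

# the main study cohort: 12 subjects, 2 h each, default effect sizes
study_cohort <- function() {
  cached("study_cohort", function() {
    generate_cohort(12, duration_h = 2, seed = 101)
  })
}

study_features <- function() {
  cached("study_features", function() {
    cohort_features(study_cohort())
  })
}

study_cv <- function() {
  cached("study_cv", function() {
    run_nested_cv(study_features(), sets = "PWA+PPI+SpO2", k = 5, seed = 7)
  })
}

# same sampling design with all event-locked physiology disabled
null_cohort <- function() {
  cached("null_cohort", function() {
    base <- synth_config(pwa_drop_frac = 0, ppi_shortening_frac = 0,
                         desat_depth_pct = 0)
    generate_cohort(12, duration_h = 2, seed = 101, base_config = base)
  })
}

null_features <- function() {
  cached("null_features", function() {
    cohort_features(null_cohort())
  })
}

# small recording reused by preprocessing/feature tests
small_recording <- function(seed = 3, duration_h = 0.5, ...) {
  key <- paste0("rec_", seed, "_", duration_h, "_",
                paste(c(...), collapse = "_"))
  cached(key, function() {
    generate_recording(synth_config(duration_h = duration_h, seed = seed, ...))
  })
}

small_prep <- function(seed = 3, duration_h = 0.5, ...) {
  key <- paste0("prep_", seed, "_", duration_h, "_",
                paste(c(...), collapse = "_"))
  cached(key, function() {
    preprocess_recording(small_recording(seed, duration_h, ...))
  })
}
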