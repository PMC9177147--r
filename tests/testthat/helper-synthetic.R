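# Shared fixtures: small synthetic experiments, built once per test run.

tiny_config <- function(seed = 11, ...) {
  ground_truth_config(n_subjects = 2, n_parcels = 8, vertices_per_parcel = 10,
                      movie_durations_s = seq(90, 180, length.out = 10),
                      seed = seed, ...)
}

# a slightly larger cohort for group-inference sanity checks
signal_config <- function(seed = 21, ...) {
  ground_truth_config(n_subjects = 8, n_parcels = 8, vertices_per_parcel = 10,
                      movie_durations_s = seq(90, 180, length.out = 10),
                      seed = seed, ...)
}

.fixture_cache <- new.env(parent = emptyenv())

cached_experiment <- function(key, config, preprocess = TRUE) {
  if (is.null(.fixture_cache[[key]])) {
    exp <- generate_experiment(config)
    if (preprocess) exp <- preprocess_experiment(exp)
    .fixture_cache[[key]] <- exp
  }
  .fixture_cache[[key]]
}

tiny_experiment <- function() cached_experiment("tiny", tiny_config())
signal_experiment <- function() cached_experiment("signal", signal_config())

# an empty run for window-arithmetic tests
blank_run <- function(n_trs, tr_s = 1.5, n_vertices = 1, trim_offset_s = 0) {
  run_data(matrix(0, n_vertices, n_trs), subject = "s01", phase = "encoding",
           run = 1, tr_s = tr_s, trim_offset_s = trim_offset_s)
}

cosine <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))
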