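# Shared fixtures.  Heavy objects (the trained tiny model, benchmark cases)
# are built once per test run and memoised here.

.fixtures <- new.env(parent = emptyenv())

# Canonical desk-scale study conditions: 64x64 frames, 300 synthetic pairs,
# 30-epoch tiny profile, fixed seed.
tiny_study_seed <- function() 7L
tiny_n_pairs <- function() 300L

get_tiny_fit <- function() {
  if (is.null(.fixtures$fit)) {
    samples <- generate_training_set(tiny_n_pairs(), seed = tiny_study_seed())
    cfg <- training_config("tiny", seed = tiny_study_seed())
    .fixtures$fit <- train_all(samples, cfg)
  }
  .fixtures$fit
}

get_tiny_models <- function() {
  fit <- get_tiny_fit()
  fit[c("classifier", "tension", "compression", "rigid")]
}

get_benchmark_cases <- function(noise_scale) {
  key <- paste0("cases_", noise_scale)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- generate_test_cases(seed = tiny_study_seed(),
                                            noise_scale = noise_scale)
  .fixtures[[key]]
}

# small random strain-field pair for metric oracles
random_field <- function(h, w, sd = 0.05, seed = 1) {
  with_seed <- get("with_seed", asNamespace("strainkit"))
  with_seed(seed, strain_field(matrix(rnorm(h * w, sd = sd), h, w),
                               matrix(rnorm(h * w, sd = sd), h, w),
                               matrix(rnorm(h * w, sd = sd), h, w)))
}
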