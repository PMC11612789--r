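# Shared fixtures. Everything is generated in code; heavier artifacts are
# memoized so several test files can share one computation.

.fixtures <- new.env(parent = emptyenv())

SR <- 200000

# A small synthetic study plan (tables only, no audio) for bookkeeping and
# context tests.
small_plan <- function() {
  if (is.null(.fixtures$plan)) {
    .fixtures$plan <- generate_experiment(small_config(), seed = 7L)
  }
  .fixtures$plan
}

small_config <- function(...) {
  experiment_config(
    n_calls = c(scream = 10, screech = 10, screech_scream = 6, chirp = 6),
    n_experiments = 2,
    phase_min = c(closed_door = 0.2, open_door = 0.8),
    n_closed_calls = 2, ...)
}

# The full-size seeded study driven through the whole pipeline; used by the
# repertoire-recovery and call-type acceptance tests.
full_pipeline_result <- function() {
  if (is.null(.fixtures$pipeline)) {
    .fixtures$pipeline <- suppressWarnings(
      run_pipeline(pipeline_config(seed = 2L)))
  }
  .fixtures$pipeline
}

# A call embedded in background noise, for segmentation tests.
embed_in_noise <- function(waves, onsets_s, total_s, sr = SR,
                           noise_rms = 0.006, seed = 99) {
  x <- withr::with_seed(seed, stats::rnorm(round(total_s * sr), 0, noise_rms))
  for (i in seq_along(waves)) {
    a <- round(onsets_s[i] * sr) + 1
    x[a:(a + length(waves[[i]]) - 1)] <-
      x[a:(a + length(waves[[i]]) - 1)] + waves[[i]]
  }
  x
}

sine_wave <- function(freq_hz, dur_s, sr = SR, amp = 0.5) {
  amp * sin(2 * pi * freq_hz * (seq_len(round(dur_s * sr)) - 1) / sr)
}
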