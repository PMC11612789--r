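# Synthetic call generator: waveform contracts, presets, determinism.

test_that("tonal call length, F0 round-trip and error contracts", {
  spec <- call_spec("scream", duration = 0.16)
  x <- synth_tonal_call(spec, SR)
  expect_length(x, 32000)

  # constant-F0 scream: oracle is the zero-crossing rate of the pure tone
  pure <- shrewvoc:::synth_tonal_core(0.16, 24.5, 24.5, "linear", 0.5, SR,
                                      n_harmonics = 1)
  zc <- sum(diff(sign(pure)) != 0)
  f0_zc <- zc / 2 / 0.16 / 1000                 # kHz
  expect_lt(abs(f0_zc - 24.5) / 24.5, 0.02)

  # the tracker recovers the same frequency from the 3-harmonic call
  spec245 <- call_spec("scream", f0_start = 24.5, f0_end = 24.5)
  tr <- track_pitch(synth_tonal_call(spec245, SR), SR)
  expect_lt(abs(mean(tr$f0_khz, na.rm = TRUE) - 24.5) / 24.5, 0.02)

  expect_error(synth_tonal_call(call_spec("scream", f0_start = 120,
                                          f0_end = 120), SR),
               "Nyquist")
  expect_error(call_spec("scream", duration = -1), "positive")
})

test_that("adult and pup scream presets differ as in the repertoire", {
  adult <- call_spec("scream", "adult")
  pup <- call_spec("scream", "pup")
  expect_gt(pup$f0_mean_target, adult$f0_mean_target)
  expect_gt(pup$duration, adult$duration)
  # and the rendered calls carry those differences
  tr_a <- track_pitch(synth_tonal_call(adult, SR), SR)
  tr_p <- track_pitch(synth_tonal_call(pup, SR), SR)
  expect_gt(mean(tr_p$f0_khz, na.rm = TRUE), mean(tr_a$f0_khz, na.rm = TRUE))
})

test_that("screech is a seeded tremolo noise burst with no stable pitch", {
  spec <- call_spec("screech", tremolo_rate = 80)
  x <- synth_screech(spec, SR, seed = 3)
  # oracle: DFT of the rectified envelope peaks at the tremolo rate
  env <- abs(x)
  p <- Mod(stats::fft(env - mean(env)))^2
  f <- (seq_along(env) - 1) / length(env) * SR
  band <- f > 10 & f < 400
  expect_lt(abs(f[band][which.max(p[band])] - 80), 12)

  tr <- track_pitch(x, SR)
  expect_equal(100 * mean(tr$voiced), 0)

  expect_identical(synth_screech(spec, SR, seed = 3), x)  # determinism
  expect_false(identical(synth_screech(spec, SR, seed = 4), x))
  expect_error(synth_screech(call_spec("screech", noise_band = c(45, 5)), SR),
               "noise_band")
})

test_that("screech-scream interpolates between its parent types", {
  spec <- call_spec("screech_scream", tonal_fraction = 0.5)
  x <- synth_screech_scream(spec, SR, seed = 2)
  tr <- track_pitch(x, SR)
  expect_lt(abs(100 * mean(tr$voiced) - 50), 10)

  # limiting cases collapse to the pure types
  s1 <- call_spec("screech_scream", tonal_fraction = 1 - 1e-9)
  tonal <- shrewvoc:::synth_tonal_core(s1$duration, s1$f0_start, s1$f0_end,
                                       s1$contour, s1$amplitude, SR)
  expect_equal(synth_screech_scream(s1, SR, seed = 5), tonal)
  s0 <- call_spec("screech_scream", tonal_fraction = 1e-9)
  noisy <- shrewvoc:::synth_screech_core(s0$duration, s0$noise_band,
                                         s0$tremolo_rate, s0$amplitude, SR,
                                         seed = 5,
                                         tremolo_depth = s0$tremolo_depth)
  expect_equal(synth_screech_scream(s0, SR, seed = 5), noisy)

  expect_error(call_spec("screech_scream", tonal_fraction = 0),
               "strictly inside")
  expect_error(call_spec("screech_scream", tonal_fraction = 1),
               "strictly inside")
})

test_that("pup chirps support an arch contour and sub-50 ms gaps", {
  spec <- call_spec("chirp", "pup", gap_ms = 20)
  x <- synth_tonal_call(spec, SR)
  n <- length(x)
  # the inserted mid-call gap is silent
  mid <- round(n / 2)
  expect_true(all(x[(mid - 5):(mid + 5)] == 0))
  expect_error(call_spec("chirp", "pup", gap_ms = 60), "50 ms")

  # arch contour: instantaneous F0 peaks mid-call
  tr <- track_pitch(synth_tonal_call(call_spec("chirp", "pup"), SR), SR)
  v <- which(tr$voiced)
  peak_pos <- tr$frame_times[v][which.max(tr$f0_khz[v])]
  expect_gt(peak_pos, 0.25 * spec$duration)
  expect_lt(peak_pos, 0.75 * spec$duration)
})
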