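# Acoustic parameter extraction: pitch tracking, tonality, F0 statistics,
# spectral moments, formants, and the availability-masked feature table.

test_that("pitch tracker separates periodic from aperiodic signals", {
  tone <- sine_wave(20000, 0.1)
  tr <- track_pitch(tone, SR)
  expect_equal(mean(tr$voiced), 1)
  expect_lt(abs(mean(tr$f0_khz) - 20) / 20, 0.02)

  noise <- withr::with_seed(8, rnorm(0.1 * SR, 0, 0.3))
  expect_lt(mean(track_pitch(noise, SR)$voiced), 0.05)

  ss <- synth_screech_scream(call_spec("screech_scream",
                                       tonal_fraction = 0.5), SR, seed = 4)
  expect_lt(abs(100 * mean(track_pitch(ss, SR)$voiced) - 50), 10)

  # sub-window segment: degenerate single-frame track
  short <- sine_wave(20000, 0.0005)
  tr_s <- track_pitch(short, SR)
  expect_true(tr_s$degenerate)
  expect_length(tr_s$voiced, 1)
})

test_that("tonality measures hit their analytic limits", {
  # stated ratio: 8 of 10 frames voiced -> 80%
  tone <- sine_wave(20000, 0.1)
  tr <- track_pitch(tone, SR)
  fake <- tr
  for (f in c("frame_times", "f0_khz", "voiced", "strength", "frame_rms")) {
    fake[[f]] <- fake[[f]][1:10]
  }
  fake$voiced <- rep(c(TRUE, FALSE), c(8, 2))
  ton <- tonality_features(tone, SR, fake)
  expect_equal(ton$voiced_percentage, 80)

  noise <- withr::with_seed(9, rnorm(0.1 * SR, 0, 0.3))
  flat <- tonality_features(noise, SR, track_pitch(noise, SR))
  expect_gte(flat$wiener_entropy_linear, 0.85)
  expect_lte(flat$wiener_entropy_linear, 1.0)

  pure <- tonality_features(tone, SR, tr)
  expect_lt(pure$wiener_entropy_db, -20)
  expect_gt(pure$hnr_db, 20)
  expect_equal(pure$hnr_linear, 10^(pure$hnr_db / 10))

  silent <- tonality_features(numeric(4000), SR,
                              track_pitch(sine_wave(20000, 0.02), SR))
  expect_true(silent$undefined)
})

test_that("F0 contour statistics match the analytic contour", {
  chirp <- shrewvoc:::synth_tonal_core(0.1, 15, 25, "linear", 0.5, SR,
                                       n_harmonics = 1)
  tr <- track_pitch(chirp, SR)
  f0 <- f0_features(tr, duration = 0.1)
  expect_lt(abs(f0$min_f0 - 15), 0.5)
  expect_lt(abs(f0$max_f0 - 25), 0.5)
  expect_lt(abs(f0$mean_f0 - 20), 0.5)
  expect_lt(abs(f0$mean_abs_slope - 100) / 100, 0.05)
  expect_gt(f0$time_of_max_f0, 0.09)

  const <- track_pitch(sine_wave(24000, 0.05), SR)
  fc <- f0_features(const, duration = 0.05)
  expect_lt(fc$sd_f0, 0.05)
  expect_lt(fc$mean_abs_slope, 20)

  # fewer than 2 voiced frames: unavailable, not an error
  tr1 <- tr
  tr1$voiced[-1] <- FALSE
  expect_false(f0_features(tr1, 0.1)$available)
})

test_that("spectral moments equal the brute-force weighted sums", {
  withr::with_seed(3, {
    for (i in 1:20) {
      p <- runif(64)
      f <- sort(runif(64, 0, 100))
      m <- spectral_moments(p, f)
      # oracle: direct weighted sums over the discrete spectrum
      w <- p / sum(p)
      cog <- sum(w * f)
      m2 <- sum(w * (f - cog)^2)
      expect_equal(m$cog, cog, tolerance = 1e-9)
      expect_equal(m$spectral_sd, sqrt(m2), tolerance = 1e-9)
      expect_equal(m$skewness, sum(w * (f - cog)^3) / m2^1.5,
                   tolerance = 1e-9)
      expect_equal(m$kurtosis, sum(w * (f - cog)^4) / m2^2 - 3,
                   tolerance = 1e-9)
    }
  })

  # ideal flat spectrum on [0, B]: uniform-distribution moments
  B <- 80
  f <- seq(0.1, B, length.out = 2000)
  m <- spectral_moments(rep(1, 2000), f)
  expect_lt(abs(m$cog - B / 2), 0.2)
  expect_lt(abs(m$spectral_sd - B / sqrt(12)), 0.2)
  expect_lt(abs(m$skewness), 0.01)

  sh <- spectral_shape(sine_wave(20000, 0.05), SR)
  expect_lt(abs(sh$cog - 20), 0.1)
  expect_lt(sh$spectral_sd, 0.5)

  two <- sine_wave(10000, 0.05) + sine_wave(30000, 0.05)
  sh2 <- spectral_shape(two, SR)
  expect_lt(abs(sh2$cog - 20), 0.2)
  expect_lt(abs(sh2$skewness), 0.05)
})

test_that("LPC resonance estimation recovers a known pole", {
  r <- 0.98; th <- 2 * pi * 15000 / SR
  y <- withr::with_seed(2, as.numeric(
    stats::filter(rnorm(40000), c(2 * r * cos(th), -r^2),
                  method = "recursive")))
  fm <- formant_features(y / max(abs(y)), SR)
  expect_lt(abs(fm$f1 - 15) / 15, 0.1)    # pole frequency oracle
  found <- c(fm$f1, fm$f2, fm$f3)
  bws <- c(fm$bw1, fm$bw2, fm$bw3)
  expect_true(all(found < fm$ceiling_khz, na.rm = TRUE))
  expect_true(all(bws > 0, na.rm = TRUE))
  # vocal-tract scaling: 1.2 cm tube -> ~80 kHz ceiling
  expect_equal(fm$ceiling_khz, 5.5 * 17.5 / 1.2, tolerance = 1e-9)
})

test_that("duration and peak time are exact and scale-invariant", {
  x <- sine_wave(20000, 0.16)
  tf <- time_features(x, SR)
  expect_equal(tf$duration, 0.16)

  # envelope peaking at the start
  decay <- exp(-seq(0, 10, length.out = 4000)) * sine_wave(20000, 0.02)
  expect_lt(time_features(decay, SR)$time_of_peak_amplitude, 0.002)

  # a designed peak at 40 ms, within one frame
  env <- exp(-abs(seq_len(0.1 * SR) / SR - 0.04) * 80)
  shaped <- sine_wave(20000, 0.1) * env
  expect_lt(abs(time_features(shaped, SR)$time_of_peak_amplitude - 0.04),
            0.002)
  expect_equal(time_features(shaped * 0.1, SR)$time_of_peak_amplitude,
               time_features(shaped, SR)$time_of_peak_amplitude)
})

test_that("the feature table applies availability and quality rules", {
  scream <- synth_tonal_call(call_spec("scream"), SR)
  screech <- synth_screech(call_spec("screech"), SR, seed = 1)
  clipped <- 2.5 * synth_tonal_call(call_spec("scream"), SR)
  rec <- list(samples = embed_in_noise(
    list(scream, screech, clipped), c(0.2, 0.6, 1.0), 1.6),
    sample_rate = SR)
  rec$samples <- pmax(-1, pmin(1, rec$samples))
  segs <- tibble::tibble(
    onset = c(0.2, 0.6, 1.0),
    offset = c(0.2 + 0.16, 0.6 + 0.11, 1.0 + 0.16),
    call_id = c("scream1", "screech1", "clipped1"))
  tab <- extract_feature_table(segs, rec)

  expect_equal(nrow(tab), 2)                       # clipped call excluded
  excl <- attr(tab, "exclusions")
  expect_equal(excl$call_id, "clipped1")
  expect_equal(excl$reason, "clipped")

  sc <- tab[tab$call_id == "scream1", ]
  expect_equal(sc$tonality_class, "tonal")
  expect_false(is.na(sc$mean_f0))
  expect_true(is.na(sc$f1))                        # no formants for tonal

  nz <- tab[tab$call_id == "screech1", ]
  expect_equal(nz$tonality_class, "non_tonal")
  expect_true(is.na(nz$mean_f0))                   # no F0 set for non-tonal
  expect_false(is.na(nz$f1))

  # 22 acoustic parameters present as columns
  expect_true(all(shrewvoc:::FEATURE_PARAMS %in% names(tab)))
  expect_length(shrewvoc:::FEATURE_PARAMS, 22)
})
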