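# Acoustic parameter extraction: autocorrelation pitch tracking, tonality
# measures (voiced percentage, HNR, Wiener entropy), F0 contour statistics,
# spectral moments, LPC formant-like resonances, and assembly of the
# 22-parameter feature table with per-tonality-class availability.

ALL_CALL_PARAMS <- c("duration", "time_of_peak_amplitude", "voiced_percentage",
                     "hnr", "wiener_entropy", "cog", "spectral_sd",
                     "skewness", "kurtosis")
TONAL_PARAMS <- c("time_of_min_f0", "time_of_max_f0", "min_f0", "max_f0",
                  "mean_f0", "sd_f0", "mean_abs_slope")
FORMANT_PARAMS <- c("f1", "bw1", "f2", "bw2", "f3", "bw3")
FEATURE_PARAMS <- c(ALL_CALL_PARAMS, TONAL_PARAMS, FORMANT_PARAMS)

#' Pitch-tracker settings
#'
#' Frames are 2 ms with a 0.5 ms hop: at 200 kHz sampling a 2 ms window
#' holds at least 10 periods of any F0 above 5 kHz, which keeps the
#' autocorrelation peak sharp for ultrasonic calls.
#'
#' @param win_s analysis window (s).
#' @param hop_s frame hop (s).
#' @param f0_min_khz,f0_max_khz F0 search range in kHz (default 5-100,
#'   clipped to Nyquist).
#' @param voiced_threshold a frame is voiced iff its taper-corrected
#'   normalized autocorrelation peak is at least this strong.
#' @param energy_floor_rel frames with RMS below this fraction of the
#'   loudest frame are never voiced (guards silent gaps).
#' @param min_voiced_run pitch-continuity constraint: voiced frames must
#'   occur in runs of at least this many consecutive frames (default 3,
#'   i.e. 1.5 ms at the default hop); isolated periodicity flickers in noise
#'   are not a visible fundamental.
#' @return list of class `pitch_config`.
#' @export
pitch_config <- function(win_s = 0.002, hop_s = 0.0005,
                         f0_min_khz = 5, f0_max_khz = 100,
                         voiced_threshold = 0.45,
                         energy_floor_rel = 0.02,
                         min_voiced_run = 3L) {
  structure(list(win_s = win_s, hop_s = hop_s, f0_min_khz = f0_min_khz,
                 f0_max_khz = f0_max_khz, voiced_threshold = voiced_threshold,
                 energy_floor_rel = energy_floor_rel,
                 min_voiced_run = as.integer(min_voiced_run)),
            class = "pitch_config")
}

#' Track the fundamental frequency of a call segment
#'
#' Per-frame autocorrelation pitch tracking. Each Hann-windowed frame is
#' autocorrelated via FFT; the normalized autocorrelation is taper-corrected
#' by the window autocorrelation (Boersma's method), and the F0 candidate is
#' the smallest-lag local maximum within 15% of the global peak in the search
#' range (this picks the true period rather than one of its multiples, which
#' carry equal correlation in a stationary harmonic call). The peak lag is
#' refined by parabolic interpolation. A frame is voiced iff the peak
#' strength reaches `voiced_threshold`: pure tones give all-voiced tracks at
#' the tone frequency, broadband noise (near-)zero voiced frames.
#'
#' @param samples waveform of one call segment.
#' @param sample_rate Hz.
#' @param config a [pitch_config()].
#' @return A list of class `frame_track`: `frame_times` (s, frame centers
#'   from segment onset), `f0_khz` (NA where unvoiced), `voiced`, `strength`
#'   (autocorrelation peak), `frame_rms`, and `degenerate` (TRUE when the
#'   segment was shorter than one analysis window).
#' @export
track_pitch <- function(samples, sample_rate, config = pitch_config()) {
  stopifnot(length(samples) >= 2)
  win <- max(4L, round(config$win_s * sample_rate))
  hop <- max(1L, round(config$hop_s * sample_rate))
  degenerate <- length(samples) < win
  win <- min(win, length(samples))
  starts <- frame_starts(length(samples), win, hop)
  nf <- length(starts)
  idx <- outer(seq_len(win) - 1L, starts, `+`)
  frames <- matrix(samples[idx], nrow = win)
  frames <- sweep(frames, 2, colMeans(frames))
  rms <- sqrt(colMeans(frames^2))
  w <- hann(win)
  nfft <- 2^ceiling(log2(2 * win))
  padded <- matrix(0, nfft, nf)
  padded[seq_len(win), ] <- frames * w
  spec <- stats::mvfft(padded)
  acf <- Re(stats::mvfft(Mod(spec)^2, inverse = TRUE)) / nfft
  # taper correction: divide by the window's own normalized autocorrelation
  wp <- c(w, rep(0, nfft - win))
  wacf <- Re(stats::fft(Mod(stats::fft(wp))^2, inverse = TRUE)) / nfft
  nyq_khz <- sample_rate / 2000
  f0_max <- min(config$f0_max_khz, nyq_khz)
  lag_min <- max(2L, floor(sample_rate / (f0_max * 1000)))
  lag_max <- min(win - 1L, ceiling(sample_rate / (config$f0_min_khz * 1000)))
  if (lag_max <= lag_min + 1L) stop("F0 search range too narrow at this sample rate")
  lags <- lag_min:lag_max
  r0 <- acf[1, ]
  r0[r0 <= 0] <- Inf
  r <- acf[lags + 1L, , drop = FALSE] / rep(r0, each = length(lags))
  r <- r / (wacf[lags + 1L] / wacf[1])
  r <- pmin(r, 0.99999)
  # smallest-lag local maximum within 15% of each frame's global peak
  nl <- length(lags)
  peak <- apply(r, 2, max)
  is_lmax <- rbind(r[1, , drop = FALSE] > r[2, , drop = FALSE],
                   r[2:(nl - 1), , drop = FALSE] >= r[1:(nl - 2), , drop = FALSE] &
                   r[2:(nl - 1), , drop = FALSE] >= r[3:nl, , drop = FALSE],
                   r[nl, , drop = FALSE] > r[nl - 1, , drop = FALSE])
  cand <- is_lmax & r >= rep(0.85 * peak, each = nl)
  cand[, peak <= 0] <- FALSE
  pick <- rep(NA_integer_, nf)
  has <- colSums(cand) > 0
  pick[has] <- apply(cand[, has, drop = FALSE], 2, which.max)  # first TRUE
  f0 <- rep(NA_real_, nf); strength <- rep(0, nf)
  ok <- which(!is.na(pick))
  if (length(ok) > 0) {
    li <- pick[ok]
    rv <- r[cbind(li, ok)]
    lag_star <- as.numeric(lags[li])
    # parabolic refinement where neighbours exist
    interior <- li > 1 & li < nl
    if (any(interior)) {
      ii <- ok[interior]; lii <- pick[ii]
      y1 <- r[cbind(lii - 1L, ii)]; y2 <- r[cbind(lii, ii)]
      y3 <- r[cbind(lii + 1L, ii)]
      denom <- y1 - 2 * y2 + y3
      delta <- ifelse(abs(denom) > 1e-12, 0.5 * (y1 - y3) / denom, 0)
      delta <- pmax(-0.5, pmin(0.5, delta))
      lag_star[interior] <- lags[lii] + delta
      rv[interior] <- y2 - 0.25 * (y1 - y3) * delta
    }
    f0[ok] <- sample_rate / lag_star / 1000
    strength[ok] <- rv
  }
  voiced <- strength >= config$voiced_threshold &
    rms >= config$energy_floor_rel * max(rms) &
    !is.na(f0) & f0 >= config$f0_min_khz & f0 <= f0_max
  if (config$min_voiced_run > 1 && any(voiced)) {
    r <- rle(voiced)
    r$values[r$values & r$lengths < config$min_voiced_run] <- FALSE
    voiced <- inverse.rle(r)
  }
  f0[!voiced] <- NA_real_
  structure(list(
    frame_times = (starts - 1 + win / 2) / sample_rate,
    f0_khz = f0, voiced = voiced, strength = strength, frame_rms = rms,
    degenerate = degenerate, sample_rate = sample_rate,
    win = win, hop = hop), class = "frame_track")
}

#' Tonality measures of a call
#'
#' Voiced percentage is the share of voiced frames among all frames. HNR is
#' computed per frame from the normalized autocorrelation peak r as
#' 10 log10(r / (1 - r)), averaged over frames, and linearized as
#' 10^(dB/10). Wiener entropy is the spectral flatness of the Welch-averaged
#' power spectrum of the call (geometric over arithmetic mean; 1 = white
#' noise, near 0 = pure tone), reported both in dB (<= 0) and linear.
#'
#' @param samples call segment waveform.
#' @param sample_rate Hz.
#' @param track the segment's [track_pitch()] result.
#' @return list with `voiced_percentage`, `hnr_db`, `hnr_linear`,
#'   `wiener_entropy_db`, `wiener_entropy_linear`, `undefined` (TRUE for a
#'   zero-energy segment, all measures NA).
#' @export
tonality_features <- function(samples, sample_rate, track) {
  stopifnot(inherits(track, "frame_track"))
  if (all(samples == 0)) {
    return(list(voiced_percentage = NA_real_, hnr_db = NA_real_,
                hnr_linear = NA_real_, wiener_entropy_db = NA_real_,
                wiener_entropy_linear = NA_real_, undefined = TRUE))
  }
  voiced_pct <- 100 * mean(track$voiced)
  r <- pmin(pmax(track$strength, 1e-4), 1 - 1e-4)
  hnr_db <- mean(10 * log10(r / (1 - r)))
  pw <- welch_power(samples, sample_rate, track$win, track$hop)
  p <- pw$power
  eps <- max(p) * 1e-12
  flat <- exp(mean(log(p + eps))) / mean(p + eps)
  list(voiced_percentage = voiced_pct,
       hnr_db = hnr_db, hnr_linear = 10^(hnr_db / 10),
       wiener_entropy_db = 10 * log10(flat), wiener_entropy_linear = flat,
       undefined = FALSE)
}

# Welch-averaged one-sided power spectrum (Hann window, DC bin dropped).
welch_power <- function(samples, sample_rate, win = NULL, hop = NULL) {
  n <- length(samples)
  win <- min(win %||% 512L, n)
  hop <- hop %||% max(1L, win %/% 4L)
  starts <- frame_starts(n, win, hop)
  idx <- outer(seq_len(win) - 1L, starts, `+`)
  frames <- matrix(samples[idx], nrow = win) * hann(win)
  nfft <- 2^ceiling(log2(win))
  padded <- matrix(0, nfft, length(starts))
  padded[seq_len(win), ] <- frames
  p <- rowMeans(Mod(stats::mvfft(padded))^2)
  half <- 2:(nfft %/% 2 + 1)          # drop DC, keep up to Nyquist
  list(power = p[half],
       freq_khz = (half - 1) / nfft * sample_rate / 1000)
}

#' F0 contour statistics
#'
#' Statistics over the voiced frames of a track: extremes, mean, standard
#' deviation, the times (from call onset) at which the minimum and maximum
#' occur, and the mean absolute slope — the sum of absolute F0 differences
#' between consecutive voiced detection points divided by the call duration
#' (kHz/s). With fewer than two voiced frames the F0 set is unavailable
#' (`available = FALSE`, all values NA), which is a contract, not an error.
#'
#' @param track a [track_pitch()] result.
#' @param duration call duration in seconds (denominator of the slope).
#' @return list with `min_f0`, `max_f0`, `mean_f0`, `sd_f0` (kHz),
#'   `time_of_min_f0`, `time_of_max_f0` (s), `mean_abs_slope` (kHz/s),
#'   `available`.
#' @export
f0_features <- function(track, duration = max(track$frame_times)) {
  stopifnot(inherits(track, "frame_track"))
  v <- which(track$voiced)
  if (length(v) < 2) {
    return(list(min_f0 = NA_real_, max_f0 = NA_real_, mean_f0 = NA_real_,
                sd_f0 = NA_real_, time_of_min_f0 = NA_real_,
                time_of_max_f0 = NA_real_, mean_abs_slope = NA_real_,
                available = FALSE))
  }
  f0 <- track$f0_khz[v]
  t <- track$frame_times[v]
  list(min_f0 = min(f0), max_f0 = max(f0), mean_f0 = mean(f0),
       sd_f0 = stats::sd(f0),
       time_of_min_f0 = t[which.min(f0)], time_of_max_f0 = t[which.max(f0)],
       mean_abs_slope = sum(abs(diff(f0))) / duration,
       available = TRUE)
}

#' Weighted spectral moments
#'
#' Direct power-weighted moments of a discrete spectrum: center of gravity
#' (first moment), spectral standard deviation, standardized skewness, and
#' excess kurtosis (0 for a Gaussian-shaped spectrum).
#'
#' @param power non-negative spectral weights.
#' @param freq_khz frequencies of the bins in kHz.
#' @return list with `cog`, `spectral_sd` (kHz), `skewness`, `kurtosis`.
#' @export
spectral_moments <- function(power, freq_khz) {
  stopifnot(length(power) == length(freq_khz), all(power >= 0))
  tot <- sum(power)
  if (tot <= 0) {
    return(list(cog = NA_real_, spectral_sd = NA_real_,
                skewness = NA_real_, kurtosis = NA_real_))
  }
  w <- power / tot
  cog <- sum(w * freq_khz)
  m2 <- sum(w * (freq_khz - cog)^2)
  m3 <- sum(w * (freq_khz - cog)^3)
  m4 <- sum(w * (freq_khz - cog)^4)
  list(cog = cog, spectral_sd = sqrt(m2),
       skewness = if (m2 > 0) m3 / m2^1.5 else NA_real_,
       kurtosis = if (m2 > 0) m4 / m2^2 - 3 else NA_real_)
}

#' Spectral shape of a call
#'
#' Computes the full-call periodogram (rectangular window, DC excluded) and
#' its power-weighted moments; see [spectral_moments()].
#'
#' @param samples call segment waveform.
#' @param sample_rate Hz.
#' @return list with `cog`, `spectral_sd`, `skewness`, `kurtosis` (kHz-based)
#'   and `undefined` flag for zero-energy input.
#' @export
spectral_shape <- function(samples, sample_rate) {
  n <- length(samples)
  stopifnot(n >= 4)
  if (all(samples == 0)) {
    return(c(spectral_moments(0, 0), list(undefined = TRUE)))
  }
  p <- Mod(stats::fft(samples))^2
  half <- 2:(n %/% 2 + 1)
  freq <- (half - 1) / n * sample_rate / 1000
  c(spectral_moments(p[half], freq), list(undefined = FALSE))
}

#' Formant-like resonances of a non-tonal call
#'
#' Linear-predictive (Burg) resonance estimation after pre-emphasis. The
#' formant ceiling is derived from the vocal tract length by uniform-tube
#' scaling: ceiling = 5500 Hz x 17.5 cm / `vtl_cm`, i.e. ~80.2 kHz for the
#' 1.2 cm shrew vocal tract. The three lowest resonances below the ceiling
#' (with plausible bandwidths) are returned; missing resonances are NA.
#'
#' @param samples call segment waveform.
#' @param sample_rate Hz.
#' @param vtl_cm vocal tract length in cm (default 1.2).
#' @param n_poles LPC order.
#' @param pre_emphasis first-order pre-emphasis coefficient.
#' @param max_bw_khz resonances broader than this are treated as spectral
#'   tilt, not formants.
#' @param ceiling_khz override for the formant ceiling (kHz).
#' @return list with `f1`, `bw1`, `f2`, `bw2`, `f3`, `bw3` in kHz and
#'   `ceiling_khz`.
#' @export
formant_features <- function(samples, sample_rate, vtl_cm = 1.2,
                             n_poles = 12, pre_emphasis = 0.97,
                             max_bw_khz = 10, ceiling_khz = NULL) {
  stopifnot(length(samples) > 4 * n_poles, vtl_cm > 0)
  ceiling_khz <- ceiling_khz %||% (5.5 * 17.5 / vtl_cm)
  ceiling_khz <- min(ceiling_khz, sample_rate / 2000)
  y <- samples - pre_emphasis * c(0, samples[-length(samples)])
  fit <- stats::ar.burg(y, aic = FALSE, order.max = n_poles, demean = TRUE)
  roots <- 1 / polyroot(c(1, -fit$ar))   # polyroot works in z^-1; poles are reciprocals
  ang <- Arg(roots)
  keep <- ang > 1e-6      # one of each conjugate pair
  freq_khz <- ang[keep] * sample_rate / (2 * pi) / 1000
  bw_khz <- -log(Mod(roots[keep])) * sample_rate / pi / 1000
  ok <- freq_khz > 0.2 & freq_khz < ceiling_khz & bw_khz > 0 &
    bw_khz < max_bw_khz
  freq <- sort(freq_khz[ok])
  bw <- bw_khz[ok][order(freq_khz[ok])]
  res <- rep(NA_real_, 6)
  for (i in seq_len(min(3, length(freq)))) {
    res[2 * i - 1] <- freq[i]
    res[2 * i] <- bw[i]
  }
  list(f1 = res[1], bw1 = res[2], f2 = res[3], bw2 = res[4],
       f3 = res[5], bw3 = res[6], ceiling_khz = ceiling_khz)
}

#' Duration and time of peak amplitude
#'
#' Duration is offset minus onset; the time of peak amplitude is the center
#' of the frame with the largest RMS, measured from call onset. Both are
#' invariant to overall amplitude scaling.
#'
#' @param samples call segment waveform.
#' @param sample_rate Hz.
#' @param win_s,hop_s envelope frame settings.
#' @return list with `duration` and `time_of_peak_amplitude` in seconds.
#' @export
time_features <- function(samples, sample_rate, win_s = 0.002,
                          hop_s = 0.0005) {
  stopifnot(length(samples) > 0)
  win <- max(2L, round(win_s * sample_rate))
  hop <- max(1L, round(hop_s * sample_rate))
  rms <- frame_rms(samples, win, hop)
  starts <- frame_starts(length(samples), win, hop)
  peak <- which.max(rms)
  list(duration = length(samples) / sample_rate,
       time_of_peak_amplitude = (starts[peak] - 1 + min(win, length(samples)) / 2) /
         sample_rate)
}

#' Feature-extraction settings
#'
#' @param tonal_threshold voiced-percentage boundary at or above which a call
#'   counts as tonal (default 95).
#' @param clip_level samples at or above this absolute amplitude mark a call
#'   as over-amplified (quality = low).
#' @param vtl_cm vocal tract length for the formant ceiling.
#' @param pitch a [pitch_config()].
#' @return list of class `feature_config`.
#' @export
feature_config <- function(tonal_threshold = 95, clip_level = 0.999,
                           vtl_cm = 1.2, pitch = pitch_config()) {
  structure(list(tonal_threshold = tonal_threshold, clip_level = clip_level,
                 vtl_cm = vtl_cm, pitch = pitch), class = "feature_config")
}

#' Extract the 22-parameter feature table for a set of call segments
#'
#' For every high-quality call the 22 acoustic parameters are measured with
#' availability by tonality class: tonal calls (voiced percentage at or above
#' the tonal threshold) carry the F0-contour set but no formants; non-tonal
#' (voiced percentage 0) and mixed calls carry the formant set but no F0
#' contour; the 9 parameters available for all calls (duration, time of peak
#' amplitude, voiced percentage, HNR, Wiener entropy, center of gravity,
#' spectral sd, skewness, kurtosis) are always present. HNR and Wiener
#' entropy are stored on the linear scale (dB companions in `hnr_db`,
#' `wiener_entropy_db`). Over-amplified (clipped) and overlap-flagged calls
#' are excluded from the table; exclusions are recorded in the
#' `"exclusions"` attribute.
#'
#' @param segments tibble with `onset`, `offset` (seconds) and optionally
#'   `call_id`, `individual_id`, `age_group`, `overlap` (logical),
#'   `recording_ref`.
#' @param recordings a single recording `list(samples, sample_rate)` or a
#'   named list of such recordings keyed by `segments$recording_ref`.
#' @param config a [feature_config()].
#' @return tibble with one row per high-quality call: identifiers,
#'   `tonality_class`, `quality`, the 22 parameters (frequencies in kHz,
#'   times in seconds) and dB companions. Unavailable parameters are NA.
#' @export
extract_feature_table <- function(segments, recordings,
                                  config = feature_config()) {
  if (!all(c("onset", "offset") %in% names(segments))) {
    stop("segments need onset and offset columns")
  }
  single <- is.numeric(recordings$samples %||% NULL)
  if (single) recordings <- list(.only = recordings)
  if (!"recording_ref" %in% names(segments)) {
    segments$recording_ref <- names(recordings)[1]
  }
  if (!"call_id" %in% names(segments)) {
    segments$call_id <- sprintf("call%04d", seq_len(nrow(segments)))
  }
  rows <- vector("list", nrow(segments))
  excl <- list()
  for (i in seq_len(nrow(segments))) {
    seg <- segments[i, ]
    rec <- recordings[[seg$recording_ref]]
    if (is.null(rec)) stop("segment references unknown recording: ",
                           seg$recording_ref)
    sr <- rec$sample_rate
    a <- max(1L, round(seg$onset * sr) + 1L)
    b <- min(length(rec$samples), round(seg$offset * sr))
    x <- rec$samples[a:b]
    if ("overlap" %in% names(seg) && isTRUE(seg$overlap)) {
      excl[[length(excl) + 1]] <- tibble::tibble(call_id = seg$call_id,
                                                 reason = "overlap")
      next
    }
    if (any(abs(x) >= config$clip_level)) {
      excl[[length(excl) + 1]] <- tibble::tibble(call_id = seg$call_id,
                                                 reason = "clipped")
      next
    }
    rows[[i]] <- measure_call(x, sr, seg, config)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "exclusions") <- dplyr::bind_rows(excl)
  out
}

measure_call <- function(x, sr, seg, config) {
  track <- track_pitch(x, sr, config$pitch)
  ton <- tonality_features(x, sr, track)
  tf <- time_features(x, sr)
  shape <- spectral_shape(x, sr)
  vp <- ton$voiced_percentage
  tclass <- if (is.na(vp)) NA_character_
    else if (vp >= config$tonal_threshold) "tonal"
    else if (vp == 0) "non_tonal" else "mixed"
  col <- function(name, default = NA_character_) {
    if (name %in% names(seg)) seg[[name]] else default
  }
  row <- tibble::tibble(
    call_id = seg$call_id,
    individual_id = col("individual_id"),
    age_group = col("age_group"),
    onset = seg$onset, offset = seg$offset,
    tonality_class = tclass, quality = "high",
    duration = tf$duration,
    time_of_peak_amplitude = tf$time_of_peak_amplitude,
    voiced_percentage = vp,
    hnr = ton$hnr_linear, wiener_entropy = ton$wiener_entropy_linear,
    hnr_db = ton$hnr_db, wiener_entropy_db = ton$wiener_entropy_db,
    cog = shape$cog, spectral_sd = shape$spectral_sd,
    skewness = shape$skewness, kurtosis = shape$kurtosis,
    time_of_min_f0 = NA_real_, time_of_max_f0 = NA_real_,
    min_f0 = NA_real_, max_f0 = NA_real_, mean_f0 = NA_real_,
    sd_f0 = NA_real_, mean_abs_slope = NA_real_,
    f1 = NA_real_, bw1 = NA_real_, f2 = NA_real_, bw2 = NA_real_,
    f3 = NA_real_, bw3 = NA_real_)
  if (identical(tclass, "tonal")) {
    f0 <- f0_features(track, tf$duration)
    if (f0$available) {
      row[names(f0)[names(f0) != "available"]] <-
        f0[names(f0) != "available"]
    }
  } else if (tclass %in% c("non_tonal", "mixed")) {
    fm <- formant_features(x, sr, vtl_cm = config$vtl_cm)
    row[FORMANT_PARAMS] <- fm[FORMANT_PARAMS]
  }
  row
}
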