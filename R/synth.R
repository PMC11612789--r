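# Synthetic Etruscan-shrew call generator.
#
# Four call types are emulated:
#   scream         long, weakly modulated tonal call (adult mean F0 ~24.5 kHz)
#   screech        non-tonal, band-limited noise with a tremolo (pulse) structure
#   screech_scream graded call: a screech-like part plus a scream-like part
#   chirp          short tonal call, ascending contour (adults) or a reversed-U
#                  "arch" contour with optional sub-50 ms gaps (pups)
#
# Tonal calls carry 3 harmonics decaying at -6 dB per harmonic, which gives
# realistic HNR / spectral-flatness contrast against the noisy calls without
# attempting a real vocal-tract model.

#' Specification of one synthetic call
#'
#' Builds a validated parameter set for a single call. Defaults are presets
#' per call type and age group reflecting the field description of the
#' repertoire: screams long (0.16 s adult) and tonal at ~24.5 kHz mean F0,
#' pup screams longer and higher; screeches non-tonal with a tremolo; chirps
#' short (0.03 s adult) and frequency modulated, pup chirps longer with an
#' arch contour; screech-screams combine a noisy and a tonal segment.
#'
#' @param call_type one of `"scream"`, `"screech"`, `"screech_scream"`,
#'   `"chirp"`.
#' @param age_group `"adult"` or `"pup"` (selects the preset).
#' @param duration call duration in seconds.
#' @param f0_start,f0_end fundamental-frequency contour endpoints in kHz for
#'   tonal parts; for the `"arch"` contour `f0_end` is the mid-call peak.
#' @param contour `"linear"` or `"arch"` (reversed U, used by pup chirps).
#' @param tremolo_rate amplitude-pulse rate in Hz for screech parts.
#' @param tremolo_depth modulation depth in (0, 1\]: 1 modulates to silence
#'   between pulses; the default 0.8 keeps residual energy so a screech stays
#'   one continuous sound unit.
#' @param tonal_fraction fraction of the call that is tonal: 1 for
#'   scream/chirp, 0 for screech, strictly inside (0, 1) for screech-screams.
#' @param amplitude peak amplitude on a linear scale in (0, 1\].
#' @param noise_band c(low, high) kHz band of the screech noise.
#' @param snr_db nominal signal-to-noise ratio against the recording floor.
#' @param bout_size number of chirps per bout (used by the experiment
#'   generator).
#' @param gap_ms silent intra-call gap length for pup chirps (must stay below
#'   50 ms, the pup call-merging rule); 0 disables gaps.
#' @param n_gaps number of intra-call gaps inserted when `gap_ms > 0`
#'   (default 1; a short call cannot host many gaps).
#' @return An object of class `call_spec` (a validated list).
#' @export
call_spec <- function(call_type = c("scream", "screech", "screech_scream", "chirp"),
                      age_group = c("adult", "pup"),
                      duration = NULL, f0_start = NULL, f0_end = NULL,
                      contour = NULL, tremolo_rate = NULL,
                      tremolo_depth = 0.8,
                      tonal_fraction = NULL, amplitude = 0.5,
                      noise_band = c(5, 45), snr_db = 30,
                      bout_size = NULL, gap_ms = NULL, n_gaps = 1L) {
  call_type <- match.arg(call_type)
  age_group <- match.arg(age_group)
  p <- call_presets(call_type, age_group)
  spec <- list(
    call_type = call_type, age_group = age_group,
    duration = duration %||% p$duration,
    f0_start = f0_start %||% p$f0_start,
    f0_end = f0_end %||% p$f0_end,
    contour = contour %||% p$contour,
    tremolo_rate = tremolo_rate %||% p$tremolo_rate,
    tremolo_depth = tremolo_depth,
    tonal_fraction = tonal_fraction %||% p$tonal_fraction,
    amplitude = amplitude,
    noise_band = noise_band,
    snr_db = snr_db,
    bout_size = bout_size %||% p$bout_size,
    gap_ms = gap_ms %||% p$gap_ms,
    n_gaps = as.integer(n_gaps)
  )
  spec$f0_mean_target <- mean(c(spec$f0_start, spec$f0_end))
  validate_call_spec(spec)
  structure(spec, class = "call_spec")
}

call_presets <- function(call_type, age_group) {
  presets <- list(
    scream = list(
      adult = list(duration = 0.16, f0_start = 24.0, f0_end = 25.0,
                   contour = "linear", tremolo_rate = NA_real_,
                   tonal_fraction = 1, bout_size = 1L, gap_ms = 0),
      pup   = list(duration = 0.22, f0_start = 31.0, f0_end = 29.0,
                   contour = "linear", tremolo_rate = NA_real_,
                   tonal_fraction = 1, bout_size = 1L, gap_ms = 0)),
    screech = list(
      adult = list(duration = 0.11, f0_start = NA_real_, f0_end = NA_real_,
                   contour = "linear", tremolo_rate = 80,
                   tonal_fraction = 0, bout_size = 1L, gap_ms = 0),
      pup   = list(duration = 0.11, f0_start = NA_real_, f0_end = NA_real_,
                   contour = "linear", tremolo_rate = 50,
                   tonal_fraction = 0, bout_size = 1L, gap_ms = 0)),
    screech_scream = list(
      adult = list(duration = 0.15, f0_start = 24.0, f0_end = 25.0,
                   contour = "linear", tremolo_rate = 80,
                   tonal_fraction = 0.5, bout_size = 1L, gap_ms = 0),
      pup   = list(duration = 0.15, f0_start = 30.0, f0_end = 29.0,
                   contour = "linear", tremolo_rate = 50,
                   tonal_fraction = 0.5, bout_size = 1L, gap_ms = 0)),
    chirp = list(
      adult = list(duration = 0.03, f0_start = 14.0, f0_end = 24.0,
                   contour = "linear", tremolo_rate = NA_real_,
                   tonal_fraction = 1, bout_size = 3L, gap_ms = 0),
      pup   = list(duration = 0.045, f0_start = 13.0, f0_end = 22.0,
                   contour = "arch", tremolo_rate = NA_real_,
                   tonal_fraction = 1, bout_size = 4L, gap_ms = 0))
  )
  presets[[call_type]][[age_group]]
}

validate_call_spec <- function(spec) {
  if (!is.numeric(spec$duration) || spec$duration <= 0) {
    stop("call duration must be positive, got ", spec$duration)
  }
  tf <- spec$tonal_fraction
  if (tf < 0 || tf > 1) stop("tonal_fraction must lie in [0, 1]")
  if (spec$call_type %in% c("scream", "chirp") && tf != 1) {
    stop("tonal_fraction must be 1 for ", spec$call_type)
  }
  if (spec$call_type == "screech" && tf != 0) {
    stop("tonal_fraction must be 0 for screech")
  }
  if (spec$call_type == "screech_scream" && (tf <= 0 || tf >= 1)) {
    stop("tonal_fraction must be strictly inside (0, 1) for screech_scream")
  }
  if (spec$amplitude <= 0 || spec$amplitude > 1) {
    stop("amplitude must lie in (0, 1]")
  }
  if (spec$call_type != "screech" && spec$gap_ms > 0 && spec$gap_ms >= 50) {
    stop("intra-call gaps must stay below 50 ms (pup merging rule), got ",
         spec$gap_ms, " ms")
  }
  invisible(spec)
}

# F0 contour (kHz) sampled at instants t in [0, d].
f0_contour <- function(t, d, f0_start, f0_end, contour) {
  if (contour == "arch") {
    # reversed U: edges at f0_start, mid-call peak at f0_end
    f0_start + (f0_end - f0_start) * (1 - (2 * t / d - 1)^2)
  } else {
    f0_start + (f0_end - f0_start) * t / d
  }
}

apply_ramps <- function(x, sample_rate, ramp_s = 0.002) {
  n <- length(x)
  nr <- min(round(ramp_s * sample_rate), floor(n / 5))
  if (nr >= 2) {
    ramp <- 0.5 - 0.5 * cos(pi * (seq_len(nr) - 1) / (nr - 1))
    x[seq_len(nr)] <- x[seq_len(nr)] * ramp
    x[(n - nr + 1):n] <- x[(n - nr + 1):n] * rev(ramp)
  }
  x
}

# Core harmonic synthesis shared by screams, chirps and the tonal part of
# screech-screams. Harmonics above Nyquist are dropped, never aliased.
synth_tonal_core <- function(duration, f0_start, f0_end, contour, amplitude,
                             sample_rate, n_harmonics = 3, ramp_s = 0.002) {
  n <- max(2L, round(duration * sample_rate))
  t <- (seq_len(n) - 1) / sample_rate
  nyq_khz <- sample_rate / 2000
  f0_peak <- max(f0_start, f0_end)
  if (f0_peak >= nyq_khz) {
    stop("fundamental frequency ", f0_peak, " kHz is at or above Nyquist (",
         nyq_khz, " kHz)")
  }
  f_khz <- f0_contour(t, duration, f0_start, f0_end, contour)
  phase <- 2 * pi * cumsum(f_khz * 1000) / sample_rate
  x <- numeric(n)
  for (h in seq_len(n_harmonics)) {
    if (h * f0_peak >= nyq_khz) break
    x <- x + 0.5^(h - 1) * sin(h * phase)   # -6 dB per harmonic
  }
  x <- apply_ramps(x, sample_rate, ramp_s)
  x * amplitude / max(abs(x))
}

# Band-limited noise with a raised-cosine tremolo (pulse train) envelope.
synth_screech_core <- function(duration, noise_band, tremolo_rate, amplitude,
                               sample_rate, seed, ramp_s = 0.002,
                               tremolo_depth = 0.8) {
  n <- max(2L, round(duration * sample_rate))
  if (length(noise_band) != 2 || noise_band[1] >= noise_band[2] ||
      noise_band[2] <= 0) {
    stop("noise_band must be c(low, high) kHz with low < high")
  }
  if (!is.finite(tremolo_rate) || tremolo_rate <= 0) {
    stop("tremolo_rate must be positive for screech synthesis")
  }
  x <- withr::with_seed(seed, stats::rnorm(n))
  # exact band limitation in the frequency domain
  freqs <- (seq_len(n) - 1) / n * sample_rate
  freqs <- pmin(freqs, sample_rate - freqs) / 1000   # folded, kHz
  mask <- freqs >= noise_band[1] & freqs <= noise_band[2]
  x <- Re(stats::fft(stats::fft(x) * mask, inverse = TRUE)) / n
  if (tremolo_depth <= 0 || tremolo_depth > 1) {
    stop("tremolo_depth must lie in (0, 1]")
  }
  t <- (seq_len(n) - 1) / sample_rate
  trem <- (1 - tremolo_depth) +
    tremolo_depth * (0.5 - 0.5 * cos(2 * pi * tremolo_rate * t))
  x <- x * trem
  x <- apply_ramps(x, sample_rate, ramp_s)
  x * amplitude / max(abs(x))
}

#' Synthesize a tonal call (scream or chirp)
#'
#' Produces a harmonic waveform whose instantaneous frequency follows a
#' linear (or, for pup chirps, reversed-U) contour between `f0_start` and
#' `f0_end`, with 3 harmonics decaying at -6 dB/harmonic and raised-cosine
#' onset/offset ramps. Pup chirps with `gap_ms > 0` contain silent gaps
#' shorter than 50 ms, emulating the gapped fundamental of pup calls.
#'
#' @param spec a [call_spec()] with `call_type` `"scream"` or `"chirp"`.
#' @param sample_rate sampling frequency in Hz (default 200 kHz).
#' @param seed unused for tonal calls (synthesis is deterministic); accepted
#'   for interface symmetry.
#' @return numeric waveform of `round(duration * sample_rate)` samples.
#' @export
synth_tonal_call <- function(spec, sample_rate = 200000, seed = NULL) {
  stopifnot(inherits(spec, "call_spec"))
  if (!spec$call_type %in% c("scream", "chirp")) {
    stop("synth_tonal_call handles scream/chirp, got ", spec$call_type)
  }
  x <- synth_tonal_core(spec$duration, spec$f0_start, spec$f0_end,
                        spec$contour, spec$amplitude, sample_rate)
  if (spec$gap_ms > 0) x <- insert_gaps(x, spec, sample_rate)
  x
}

# Zero out n_gaps interior stretches of gap_ms, with mini-ramps at each edge
# so the gaps do not introduce clicks. Total duration is unchanged.
insert_gaps <- function(x, spec, sample_rate) {
  n <- length(x)
  ng <- spec$n_gaps
  gap_n <- round(spec$gap_ms / 1000 * sample_rate)
  if (gap_n * ng >= n * 0.8) stop("gaps would consume most of the call")
  centers <- round(n * seq_len(ng) / (ng + 1))
  edge <- max(2L, round(0.0005 * sample_rate))
  for (ctr in centers) {
    a <- max(1L, ctr - floor(gap_n / 2))
    b <- min(n, a + gap_n - 1L)
    x[a:b] <- 0
    lo <- max(1L, a - edge); hi <- min(n, b + edge)
    if (a - lo >= 1) x[lo:(a - 1)] <- x[lo:(a - 1)] * rev(seq(0, 1, length.out = a - lo))
    if (hi - b >= 1) x[(b + 1):hi] <- x[(b + 1):hi] * seq(0, 1, length.out = hi - b)
  }
  x
}

#' Synthesize a screech (non-tonal tremolo call)
#'
#' Band-limited Gaussian noise in `spec$noise_band`, amplitude modulated with
#' a raised-cosine pulse train at `spec$tremolo_rate` ("numerous pulses"),
#' with no stable harmonic structure. Byte-identical for a fixed seed.
#'
#' @param spec a [call_spec()] with `call_type = "screech"`.
#' @param sample_rate sampling frequency in Hz.
#' @param seed integer seed for the noise generator.
#' @return numeric waveform.
#' @export
synth_screech <- function(spec, sample_rate = 200000, seed = 1L) {
  stopifnot(inherits(spec, "call_spec"))
  if (spec$call_type != "screech") {
    stop("synth_screech handles screech, got ", spec$call_type)
  }
  synth_screech_core(spec$duration, spec$noise_band, spec$tremolo_rate,
                     spec$amplitude, sample_rate, seed,
                     tremolo_depth = spec$tremolo_depth)
}

#' Synthesize a graded screech-scream
#'
#' Concatenates a screech-like noisy segment and a scream-like tonal segment.
#' The tonal segment occupies `tonal_fraction` of the duration; the two parts
#' are RMS-matched at the junction. Default order is noisy part first.
#'
#' @param spec a [call_spec()] with `call_type = "screech_scream"` and
#'   `tonal_fraction` strictly inside (0, 1).
#' @param sample_rate sampling frequency in Hz.
#' @param seed integer seed for the noisy segment.
#' @param order `"noise_first"` (default) or `"tonal_first"`.
#' @return numeric waveform.
#' @export
synth_screech_scream <- function(spec, sample_rate = 200000, seed = 1L,
                                 order = c("noise_first", "tonal_first")) {
  stopifnot(inherits(spec, "call_spec"))
  order <- match.arg(order)
  if (spec$call_type != "screech_scream") {
    stop("synth_screech_scream handles screech_scream, got ", spec$call_type)
  }
  n <- max(2L, round(spec$duration * sample_rate))
  n_tonal <- round(spec$tonal_fraction * n)
  n_noise <- n - n_tonal
  tonal <- if (n_tonal > 1) {
    synth_tonal_core(n_tonal / sample_rate, spec$f0_start, spec$f0_end,
                     spec$contour, spec$amplitude, sample_rate)
  } else numeric(n_tonal)
  noise <- if (n_noise > 1) {
    synth_screech_core(n_noise / sample_rate, spec$noise_band,
                       spec$tremolo_rate, spec$amplitude, sample_rate, seed,
                       tremolo_depth = spec$tremolo_depth)
  } else numeric(n_noise)
  # amplitude-match the parts at the junction (equal RMS)
  if (length(tonal) > 1 && length(noise) > 1) {
    r_t <- sqrt(mean(tonal^2)); r_n <- sqrt(mean(noise^2))
    if (r_n > 0) noise <- noise * r_t / r_n
  }
  x <- if (order == "noise_first") c(noise, tonal) else c(tonal, noise)
  x * spec$amplitude / max(abs(x))
}

#' Synthesize any call type from its spec
#'
#' Dispatches to [synth_tonal_call()], [synth_screech()] or
#' [synth_screech_scream()] by `spec$call_type`.
#'
#' @inheritParams synth_screech_scream
#' @return numeric waveform.
#' @export
synth_call <- function(spec, sample_rate = 200000, seed = 1L,
                       order = "noise_first") {
  switch(spec$call_type,
    scream = ,
    chirp = synth_tonal_call(spec, sample_rate, seed),
    screech = synth_screech(spec, sample_rate, seed),
    screech_scream = synth_screech_scream(spec, sample_rate, seed, order)
  )
}
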