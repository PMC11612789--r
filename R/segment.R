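# Call-unit detection from the energy envelope.

#' Segmentation settings
#'
#' @param win_s analysis window in seconds (default 2 ms).
#' @param hop_s hop between frames in seconds (default 0.5 ms).
#' @param threshold_factor detection threshold as a multiple of the median
#'   frame RMS (the noise floor in sparse recordings).
#' @param merge_gap_s pup-mode merging rule: adjacent sound units separated
#'   by less than this gap belong to one call (default 50 ms).
#' @param close_gap_s continuity closing applied in every mode: envelope
#'   dips shorter than this (default 15 ms) are within-call fluctuations —
#'   e.g. the pulse train of a tremolo call — not silence between calls.
#' @param min_dur_s candidate units shorter than this are discarded.
#' @return list of class `segment_config`.
#' @export
segment_config <- function(win_s = 0.002, hop_s = 0.0005,
                           threshold_factor = 4, merge_gap_s = 0.05,
                           close_gap_s = 0.015, min_dur_s = 0.005) {
  structure(list(win_s = win_s, hop_s = hop_s,
                 threshold_factor = threshold_factor,
                 merge_gap_s = merge_gap_s, close_gap_s = close_gap_s,
                 min_dur_s = min_dur_s),
            class = "segment_config")
}

#' Detect call units in a recording
#'
#' A call is the smallest unit of continuous sound energy above an
#' energy-envelope threshold. In pup mode, adjacent units separated by a gap
#' shorter than `merge_gap_s` (50 ms by default) are merged into one call,
#' reflecting the gapped fundamental of pup calls; in adult mode no merging
#' is applied. Onsets and offsets are snapped to frame boundaries.
#'
#' @param samples numeric waveform in \[-1, 1\].
#' @param sample_rate Hz.
#' @param age_mode `"adult"` (no merging) or `"pup"` (merge sub-50 ms gaps).
#' @param config a [segment_config()].
#' @return tibble with `onset`, `offset` (seconds, half-open intervals) and
#'   `age_mode`; zero rows for a silent recording.
#' @export
segment_calls <- function(samples, sample_rate,
                          age_mode = c("adult", "pup"),
                          config = segment_config()) {
  age_mode <- match.arg(age_mode)
  stopifnot(length(samples) > 0, sample_rate > 0)
  win <- max(2L, round(config$win_s * sample_rate))
  hop <- max(1L, round(config$hop_s * sample_rate))
  rms <- frame_rms(samples, win, hop)
  thr <- stats::median(rms) * config$threshold_factor
  above <- rms > thr & rms > 0
  if (!any(above)) {
    return(tibble::tibble(onset = numeric(), offset = numeric(),
                          age_mode = character()))
  }
  runs <- true_runs(above)
  onset <- (runs[, "start"] - 1) * hop / sample_rate
  offset <- ((runs[, "end"] - 1) * hop + win) / sample_rate
  merge_below <- function(onset, offset, gap) {
    if (length(onset) < 2) return(list(onset = onset, offset = offset))
    merged_on <- onset[1]; merged_off <- offset[1]
    for (i in 2:length(onset)) {
      if (onset[i] - merged_off[length(merged_off)] < gap) {
        merged_off[length(merged_off)] <- offset[i]
      } else {
        merged_on <- c(merged_on, onset[i])
        merged_off <- c(merged_off, offset[i])
      }
    }
    list(onset = merged_on, offset = merged_off)
  }
  m <- merge_below(onset, offset, config$close_gap_s)
  if (age_mode == "pup") {
    m <- merge_below(m$onset, m$offset, config$merge_gap_s)
  }
  onset <- m$onset; offset <- m$offset
  keep <- (offset - onset) >= config$min_dur_s
  tibble::tibble(onset = onset[keep], offset = offset[keep],
                 age_mode = age_mode)
}
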