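# Synthetic confrontation-experiment generator.
#
# generate_experiment() lays out a full synthetic study: dyads with sex
# composition / familiarity / housing factors, closed-door and open-door
# phases, an ethogram-coded behavior-event stream per experiment, and calls
# of the four types placed at non-overlapping times inside behavior events
# (chirps inside caravanning, the socio-negative types inside socio-negative
# or avoidance events). The plan is purely tabular and cheap; waveforms are
# rendered per experiment on demand with render_recording(), which keeps
# memory bounded for long recordings.

ETHOGRAM <- c("avoidance", "box", "caravanning", "combination",
              "socio_negative", "wire_mesh", "no_physical_interaction")

NEGATIVE_TYPES <- c("scream", "screech", "screech_scream")
CALL_TYPES <- c("scream", "screech", "screech_scream", "chirp")

#' Configuration of a synthetic confrontation study
#'
#' Defaults define the study conditions emulated by the generator: 600 calls
#' (200 screams, 200 screeches, 100 screech-screams, 100 chirps) across 12
#' dyad experiments with a 0.5 min closed-door and 1.5 min open-door phase,
#' 200 kHz / 16-bit recordings with a 30 dB signal-to-noise floor. Chirp
#' placement is weighted toward male-female dyads and socio-negative calls
#' toward pair-housed dyads, the two rate effects the call-rate models are
#' meant to recover.
#'
#' @param n_calls named counts per call type.
#' @param n_experiments number of dyad experiments.
#' @param phase_min named durations in minutes, `closed_door` and `open_door`.
#' @param sample_rate Hz.
#' @param snr_db nominal call-to-floor signal-to-noise ratio in dB.
#' @param pup_fraction named per-type probability that a call is a pup call.
#' @param tonal_fraction_range range of the graded screech-scream tonal
#'   fraction (drawn uniformly).
#' @param chirp_mf_multiplier placement weight of chirps in male-female
#'   dyads relative to same-sex dyads.
#' @param negative_pair_multiplier placement weight of socio-negative call
#'   types in pair-housed dyads relative to group-housed ones.
#' @param duration_cv lognormal coefficient of variation of call durations.
#' @param f0_jitter_khz s.d. of the per-call F0 endpoint jitter.
#' @param min_call_gap_s minimum silent gap between consecutive calls; kept
#'   above the 50 ms pup merging rule so distinct calls are never merged.
#' @param n_closed_calls calls placed in closed-door phases (excluded from
#'   behavior coding downstream).
#' @param n_clipped calls rendered over-amplified, to exercise the
#'   high-quality exclusion.
#' @param gap_prob_pup_chirp probability that a pup chirp carries sub-50 ms
#'   intra-call gaps.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(n_calls = c(scream = 200, screech = 200,
                                          screech_scream = 100, chirp = 100),
                              n_experiments = 12,
                              phase_min = c(closed_door = 0.5, open_door = 1.5),
                              sample_rate = 200000,
                              snr_db = 30,
                              pup_fraction = c(scream = 0.3, screech = 0.05,
                                               screech_scream = 0.05, chirp = 0.8),
                              tonal_fraction_range = c(0.05, 0.95),
                              chirp_mf_multiplier = 4,
                              negative_pair_multiplier = 2.5,
                              duration_cv = 0.18,
                              f0_jitter_khz = 1.2,
                              min_call_gap_s = 0.08,
                              n_closed_calls = 8,
                              n_clipped = 0,
                              gap_prob_pup_chirp = 0) {
  cfg <- as.list(environment())
  stopifnot(all(CALL_TYPES %in% names(cfg$n_calls)),
            all(cfg$phase_min > 0), cfg$n_experiments >= 2)
  structure(cfg, class = "experiment_config")
}

#' Generate a synthetic confrontation study with known ground truth
#'
#' Builds the full tabular plan of a synthetic study: dyad metadata, behavior
#' events, and one ground-truth row per call (type, voiced fraction, placement,
#' synthesis parameters, caller, behavioral context). The plan is fully
#' reproducible from `seed`. Waveforms are not rendered here; use
#' [render_recording()] per experiment or pass `dir` to write WAV files,
#' ground-truth/behavior/dyad CSVs and per-experiment TextGrids.
#'
#' @param config an [experiment_config()].
#' @param seed integer seed; the same seed reproduces the plan bit-identically.
#' @param dir optional output directory; when given, all artifacts are written.
#' @return An object of class `shrew_experiment` with elements
#'   `ground_truth`, `behavior_events`, `dyads`, `sample_rate`, `config`,
#'   `seed`.
#' @export
generate_experiment <- function(config = experiment_config(), seed = 1L,
                                dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  plan <- withr::with_seed(as.integer(seed), build_plan(config))
  plan$seed <- as.integer(seed)
  plan$config <- config
  class(plan) <- "shrew_experiment"
  if (!is.null(dir)) write_experiment(plan, dir)
  plan
}

build_plan <- function(cfg) {
  n_exp <- cfg$n_experiments
  exp_ids <- sprintf("exp%02d", seq_len(n_exp))

  # --- dyads ----------------------------------------------------------
  adults <- tibble::tibble(
    individual = sprintf("A%02d", 1:16),
    sex = rep(c("M", "F"), each = 8))
  sex_comp <- sample(rep(c("MM", "FF", "MF"), length.out = n_exp))
  pick <- function(comp) {
    if (comp == "MM") sample(adults$individual[adults$sex == "M"], 2)
    else if (comp == "FF") sample(adults$individual[adults$sex == "F"], 2)
    else c(sample(adults$individual[adults$sex == "M"], 1),
           sample(adults$individual[adults$sex == "F"], 1))
  }
  pairs <- lapply(sex_comp, pick)
  dyads <- tibble::tibble(
    experiment_id = exp_ids,
    individual_1 = vapply(pairs, `[`, "", 1),
    individual_2 = vapply(pairs, `[`, "", 2),
    sex_composition = sex_comp,
    familiarity = sample(c("familiar", "unfamiliar"), n_exp, replace = TRUE),
    housing_type = sample(rep(c("pair", "same_sex_group"), length.out = n_exp)),
    closed_door_min = unname(cfg$phase_min["closed_door"]),
    open_door_min = unname(cfg$phase_min["open_door"]))

  closed_s <- dyads$closed_door_min[1] * 60
  open_s <- dyads$open_door_min[1] * 60

  # --- allocate calls to experiments ----------------------------------
  w_chirp <- ifelse(dyads$sex_composition == "MF", cfg$chirp_mf_multiplier, 1)
  w_neg <- ifelse(dyads$housing_type == "pair", cfg$negative_pair_multiplier, 1)
  alloc <- list(
    scream = as.vector(stats::rmultinom(1, cfg$n_calls["scream"], w_neg)),
    screech = as.vector(stats::rmultinom(1, cfg$n_calls["screech"], w_neg)),
    screech_scream = as.vector(stats::rmultinom(1, cfg$n_calls["screech_scream"], w_neg)),
    chirp = as.vector(stats::rmultinom(1, cfg$n_calls["chirp"], w_chirp)))

  # --- per-experiment events and call placement -----------------------
  events <- list(); truth <- list()
  pup_pool <- sprintf("P%02d", 1:8)
  for (e in seq_len(n_exp)) {
    counts <- vapply(alloc, `[`, 0, e)
    specs <- draw_call_specs(counts, cfg)
    placed <- place_experiment(specs, exp_ids[e], dyads[e, ], closed_s, open_s,
                               cfg, pup_pool)
    events[[e]] <- placed$events
    truth[[e]] <- placed$truth
  }
  truth <- dplyr::bind_rows(truth)
  events <- dplyr::bind_rows(events)

  # --- closed-door calls (screams), spread over experiments ------------
  if (cfg$n_closed_calls > 0) {
    closed <- draw_call_specs(c(scream = cfg$n_closed_calls, screech = 0,
                                screech_scream = 0, chirp = 0), cfg)
    ce <- sample(exp_ids, nrow(closed), replace = TRUE)
    closed$experiment_id <- ce
    closed$onset <- stats::runif(nrow(closed), 1, closed_s - 1)
    # keep closed-door calls apart from each other within an experiment
    for (id in unique(ce)) {
      i <- which(ce == id)
      closed$onset[i] <- sort(closed$onset[i])
      while (any(diff(closed$onset[i]) < 1)) {
        closed$onset[i] <- sort(stats::runif(length(i), 1, closed_s - 1))
      }
    }
    closed$offset <- closed$onset + closed$duration
    closed$phase <- "closed_door"
    closed$context_label <- NA_character_
    closed$individual_id <- dyads$individual_1[match(ce, dyads$experiment_id)]
    truth <- dplyr::bind_rows(truth, closed)
  }

  # --- over-amplified calls for the quality filter ---------------------
  if (cfg$n_clipped > 0) {
    idx <- sample(which(truth$phase == "open_door"), cfg$n_clipped)
    truth$amplitude[idx] <- 1.6   # clips after normalization to [-1, 1]
  }
  truth$clipped <- truth$amplitude > 1

  truth <- truth[order(truth$experiment_id, truth$onset), ]
  truth$call_id <- sprintf("%s_c%03d", truth$experiment_id,
                           stats::ave(seq_len(nrow(truth)), truth$experiment_id,
                                      FUN = seq_along))
  truth$noise_seed <- NULL
  truth <- dplyr::relocate(truth, "call_id", "experiment_id", "true_type",
                           "age_group", "onset", "offset", "phase",
                           "context_label", "individual_id",
                           "true_voiced_fraction", "coarse_class")
  list(ground_truth = tibble::as_tibble(truth),
       behavior_events = tibble::as_tibble(events),
       dyads = dyads,
       sample_rate = cfg$sample_rate,
       noise_seeds = stats::setNames(
         sample.int(.Machine$integer.max - 1L, n_exp), exp_ids))
}

# Draw jittered call specs for given per-type counts (rows of a tibble).
draw_call_specs <- function(counts, cfg) {
  rows <- list()
  for (type in CALL_TYPES) {
    k <- counts[[type]]
    if (is.na(k) || k == 0) next
    age <- ifelse(stats::runif(k) < cfg$pup_fraction[[type]], "pup", "adult")
    for (i in seq_len(k)) {
      p <- call_presets(type, age[i])
      dur <- p$duration * exp(stats::rnorm(1, 0, cfg$duration_cv))
      tf <- switch(type, scream = 1, chirp = 1, screech = 0,
                   screech_scream = stats::runif(1, cfg$tonal_fraction_range[1],
                                                 cfg$tonal_fraction_range[2]))
      f0s <- if (is.na(p$f0_start)) NA_real_ else
        p$f0_start + stats::rnorm(1, 0, cfg$f0_jitter_khz)
      f0e <- if (is.na(p$f0_end)) NA_real_ else
        p$f0_end + stats::rnorm(1, 0, cfg$f0_jitter_khz)
      trem <- if (is.na(p$tremolo_rate)) NA_real_ else
        p$tremolo_rate * exp(stats::rnorm(1, 0, 0.15))
      gap <- if (type == "chirp" && age[i] == "pup" &&
                 stats::runif(1) < cfg$gap_prob_pup_chirp) 20 else 0
      rows[[length(rows) + 1]] <- tibble::tibble(
        true_type = type, age_group = age[i], duration = dur,
        f0_start = f0s, f0_end = f0e,
        contour = p$contour, tremolo_rate = trem, tonal_fraction = tf,
        amplitude = stats::runif(1, 0.35, 0.7),
        noise_band_low = 5, noise_band_high = 45,
        gap_ms = gap, n_gaps = 1L,
        call_seed = sample.int(.Machine$integer.max - 1L, 1))
    }
  }
  out <- dplyr::bind_rows(rows)
  out$true_voiced_fraction <- 100 * out$tonal_fraction
  out$coarse_class <- ifelse(out$true_type == "chirp", "short_tonal",
                      ifelse(out$tonal_fraction >= 0.5, "long_tonal", "noisy"))
  out
}

# Build a behavior-event schedule and place the experiment's calls inside it.
place_experiment <- function(specs, exp_id, dyad, closed_s, open_s, cfg,
                             pup_pool) {
  t0 <- closed_s
  t1 <- closed_s + open_s
  need_car <- sum(specs$duration[specs$true_type == "chirp"]) +
    cfg$min_call_gap_s * (sum(specs$true_type == "chirp") + 2)
  is_neg <- specs$true_type %in% NEGATIVE_TYPES
  need_neg <- sum(specs$duration[is_neg]) +
    cfg$min_call_gap_s * (sum(is_neg) + 4)

  schedule <- NULL
  for (try in 1:25) {
    cand <- draw_event_schedule(t0, t1)
    cap <- function(cats) {
      rows <- cand$category %in% cats
      sum(cand$offset[rows] - cand$onset[rows])
    }
    if (cap("caravanning") >= need_car &&
        cap(c("socio_negative", "avoidance")) >= need_neg * 1.1) {
      schedule <- cand
      break
    }
  }
  if (is.null(schedule)) {
    stop("requested calls exceed available event time in ", exp_id,
         " (need ", round(need_car + need_neg, 1), " s of host events)")
  }
  schedule$experiment_id <- exp_id
  schedule$phase <- "open_door"

  # assign each call to a host event of the right category
  host <- character(nrow(specs))
  host[specs$true_type == "chirp"] <- "caravanning"
  host[is_neg] <- ifelse(stats::runif(sum(is_neg)) < 0.85,
                         "socio_negative", "avoidance")
  ev <- schedule[schedule$category %in% c("caravanning", "socio_negative",
                                          "avoidance"), ]
  ev$free <- (ev$offset - ev$onset) - 2 * cfg$min_call_gap_s
  assign_ev <- integer(nrow(specs))
  ord <- order(-specs$duration)           # big calls first, greedy best fit
  for (i in ord) {
    ok <- which(ev$category == host[i] &
                ev$free >= specs$duration[i] + cfg$min_call_gap_s)
    if (length(ok) == 0 && host[i] %in% c("avoidance", "socio_negative")) {
      host[i] <- setdiff(c("avoidance", "socio_negative"), host[i])
      ok <- which(ev$category == host[i] &
                  ev$free >= specs$duration[i] + cfg$min_call_gap_s)
    }
    if (length(ok) == 0) {
      stop("requested calls exceed available silent time in ", exp_id)
    }
    j <- ok[which.max(ev$free[ok])]
    assign_ev[i] <- j
    ev$free[j] <- ev$free[j] - specs$duration[i] - cfg$min_call_gap_s
  }

  # place calls within each event by stick-breaking the slack into gaps
  specs$onset <- NA_real_
  for (j in unique(assign_ev)) {
    idx <- which(assign_ev == j)
    idx <- idx[sample.int(length(idx))]   # random order inside the event
    durs <- specs$duration[idx]
    span <- ev$offset[j] - ev$onset[j]
    k <- length(idx)
    slack <- span - sum(durs) - (k + 1) * cfg$min_call_gap_s
    u <- stats::runif(k + 1)
    gaps <- cfg$min_call_gap_s + slack * u / sum(u)   # k + 1 gaps
    onsets <- ev$onset[j] + cumsum(gaps[seq_len(k)]) +
      cumsum(c(0, utils::head(durs, -1)))
    specs$onset[idx] <- onsets
  }
  specs$offset <- specs$onset + specs$duration
  specs$context_label <- host
  specs$phase <- "open_door"
  specs$experiment_id <- exp_id

  # caller: adults from the dyad, pups from the pup pool
  pups <- sample(pup_pool, 2)
  specs$individual_id <- ifelse(
    specs$age_group == "pup", sample(pups, nrow(specs), replace = TRUE),
    sample(c(dyad$individual_1, dyad$individual_2), nrow(specs), replace = TRUE))
  list(events = schedule, truth = specs)
}

# A random open-door event schedule: an interaction tier that tiles the phase
# with gaps, plus a position tier (box / wire_mesh) that may overlap it.
draw_event_schedule <- function(t0, t1) {
  cats <- c("socio_negative", "caravanning", "avoidance", "combination",
            "no_physical_interaction")
  probs <- c(0.40, 0.22, 0.15, 0.03, 0.20)
  onsets <- c(); offsets <- c(); labs <- c()
  t <- t0 + stats::runif(1, 0.2, 1)
  while (t < t1 - 2) {
    dur <- stats::runif(1, 5, 10)
    dur <- min(dur, t1 - t - 0.2)
    labs <- c(labs, sample(cats, 1, prob = probs))
    onsets <- c(onsets, t)
    offsets <- c(offsets, t + dur)
    t <- t + dur + stats::runif(1, 0.2, 1.0)
  }
  inter <- tibble::tibble(category = labs, onset = onsets, offset = offsets,
                          tier = "interaction")
  npos <- sample(2:4, 1)
  pos_on <- sort(stats::runif(npos, t0, t1 - 6))
  pos <- tibble::tibble(category = sample(c("box", "wire_mesh"), npos,
                                          replace = TRUE),
                        onset = pos_on,
                        offset = pmin(pos_on + stats::runif(npos, 2, 6), t1),
                        tier = "position")
  # keep the position tier internally non-overlapping
  keep <- c(TRUE, diff(pos$onset) > 6)
  dplyr::bind_rows(inter, pos[keep, ])
}

#' Render one experiment's recording from the plan
#'
#' Synthesizes the background noise floor and all calls of one experiment and
#' mixes them at their planned onsets. Deterministic: the same plan renders
#' the same samples.
#'
#' @param experiment a `shrew_experiment` from [generate_experiment()].
#' @param experiment_id one of `experiment$dyads$experiment_id`.
#' @return A list with `samples` and `sample_rate`.
#' @export
render_recording <- function(experiment, experiment_id) {
  stopifnot(inherits(experiment, "shrew_experiment"))
  dyad <- experiment$dyads[experiment$dyads$experiment_id == experiment_id, ]
  if (nrow(dyad) != 1) stop("unknown experiment_id: ", experiment_id)
  sr <- experiment$sample_rate
  total_s <- (dyad$closed_door_min + dyad$open_door_min) * 60
  n <- round(total_s * sr)
  noise_rms <- 0.2 * 10^(-experiment$config$snr_db / 20)
  x <- withr::with_seed(experiment$noise_seeds[[experiment_id]],
                        stats::rnorm(n, 0, noise_rms))
  calls <- experiment$ground_truth[
    experiment$ground_truth$experiment_id == experiment_id, ]
  for (i in seq_len(nrow(calls))) {
    w <- render_call(calls[i, ], sr)
    a <- round(calls$onset[i] * sr) + 1
    b <- a + length(w) - 1
    if (b > n) next
    x[a:b] <- x[a:b] + w
  }
  list(samples = pmax(-1, pmin(1, x)), sample_rate = sr)
}

# Waveform of one ground-truth row.
render_call <- function(row, sample_rate) {
  amp <- min(row$amplitude, 1)      # call_spec caps amplitude at 1 ...
  spec <- call_spec(row$true_type, row$age_group,
                    duration = row$duration,
                    f0_start = if (is.na(row$f0_start)) NULL else row$f0_start,
                    f0_end = if (is.na(row$f0_end)) NULL else row$f0_end,
                    contour = row$contour,
                    tremolo_rate = if (is.na(row$tremolo_rate)) NULL else row$tremolo_rate,
                    tonal_fraction = row$tonal_fraction,
                    amplitude = amp,
                    noise_band = c(row$noise_band_low, row$noise_band_high),
                    gap_ms = row$gap_ms, n_gaps = row$n_gaps)
  w <- synth_call(spec, sample_rate, seed = row$call_seed)
  if (row$amplitude > 1) w <- w * row$amplitude   # ... over-amplified here
  w
}

#' Write all artifacts of a synthetic study to a directory
#'
#' Writes one WAV per experiment, `ground_truth.csv`, `behavior_events.csv`,
#' `dyads.csv`, and one `<experiment>_behavior.TextGrid` per experiment with
#' an interval tier named "behavior".
#'
#' @param experiment a `shrew_experiment`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "shrew_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(experiment$ground_truth, file.path(dir, "ground_truth.csv"))
  readr::write_csv(experiment$behavior_events,
                   file.path(dir, "behavior_events.csv"))
  readr::write_csv(experiment$dyads, file.path(dir, "dyads.csv"))
  for (id in experiment$dyads$experiment_id) {
    rec <- render_recording(experiment, id)
    write_wav(rec$samples, rec$sample_rate, file.path(dir, paste0(id, ".wav")))
    ev <- experiment$behavior_events[
      experiment$behavior_events$experiment_id == id, ]
    total_s <- (experiment$dyads$closed_door_min[1] +
                experiment$dyads$open_door_min[1]) * 60
    write_textgrid(ev, file.path(dir, paste0(id, "_behavior.TextGrid")),
                   xmax = total_s)
  }
  invisible(dir)
}

#' @export
print.shrew_experiment <- function(x, ...) {
  cat("Synthetic shrew vocal study\n")
  cat("  experiments:", nrow(x$dyads), " calls:", nrow(x$ground_truth), "\n")
  print(table(x$ground_truth$true_type))
  invisible(x)
}
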