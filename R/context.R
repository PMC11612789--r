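# Behavioral-context attribution: aligning calls to ethogram events,
# context and proximity shares, and call rates per experiment.

#' Default behavior priority order
#'
#' When a call falls inside several simultaneous behavior events, actual
#' interactions take precedence over events describing the animals' position
#' in the arena. Highest priority first.
#'
#' @return character vector of ethogram categories.
#' @export
behavior_priority <- function() {
  c("socio_negative", "combination", "caravanning", "avoidance",
    "box", "wire_mesh", "no_physical_interaction")
}

#' Attribute each call to a behavior
#'
#' Each call receives the single behavior of the highest-priority event that
#' contains its onset (onset-based assignment: calls may outlast short
#' events). Calls contained in no event are attributed to
#' `no_physical_interaction`.
#'
#' @param calls tibble with `experiment_id`, `onset` and any id/type
#'   columns.
#' @param events tibble with `experiment_id`, `category`, `onset`, `offset`.
#' @param priority category order, highest priority first.
#' @return `calls` with an added `behavior` column.
#' @export
align_calls <- function(calls, events, priority = behavior_priority()) {
  stopifnot(all(c("experiment_id", "onset") %in% names(calls)),
            all(c("experiment_id", "category", "onset", "offset") %in%
                  names(events)))
  unknown <- setdiff(unique(events$category), ethogram_categories())
  if (length(unknown) > 0) {
    stop("unknown behavior categories: ", paste(unknown, collapse = ", "))
  }
  rank <- stats::setNames(seq_along(priority), priority)
  behavior <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    hit <- events$experiment_id == calls$experiment_id[i] &
      events$onset <= calls$onset[i] & calls$onset[i] < events$offset
    behavior[i] <- if (any(hit)) {
      cats <- events$category[hit]
      cats[which.min(rank[cats])]
    } else "no_physical_interaction"
  }
  calls$behavior <- behavior
  calls
}

#' Proximity shares per call type
#'
#' For each call type, the percentage of calls produced while the animals
#' were in proximity (inside a proximity interval), within 1 s before or
#' after proximity, or outside. The three buckets are mutually exclusive and
#' sum to 100% per call type. Because whether the 1 s buffer counts as
#' proximity is a matter of convention, the combined tally
#' `pct_proximity_incl_buffer` is also reported.
#'
#' @param calls tibble with `experiment_id`, `onset`, `call_type`.
#' @param proximity tibble of proximity intervals with `experiment_id`,
#'   `onset`, `offset`.
#' @param buffer_s the near-proximity buffer (default 1 s).
#' @return tibble per call type with `n`, `pct_in_proximity`,
#'   `pct_within_1s`, `pct_outside`, `pct_proximity_incl_buffer`.
#' @export
proximity_shares <- function(calls, proximity, buffer_s = 1) {
  if (nrow(calls) == 0) {
    return(tibble::tibble(call_type = character(), n = integer(),
                          pct_in_proximity = numeric(),
                          pct_within_1s = numeric(),
                          pct_outside = numeric(),
                          pct_proximity_incl_buffer = numeric()))
  }
  stopifnot(all(proximity$offset > proximity$onset))
  bucket <- vapply(seq_len(nrow(calls)), function(i) {
    iv <- proximity[proximity$experiment_id == calls$experiment_id[i], ]
    t <- calls$onset[i]
    if (any(iv$onset <= t & t < iv$offset)) return("in_proximity")
    if (any(t >= iv$onset - buffer_s & t < iv$onset) ||
        any(t >= iv$offset & t < iv$offset + buffer_s)) return("within_1s")
    "outside"
  }, "")
  calls$bucket <- factor(bucket, levels = c("in_proximity", "within_1s",
                                            "outside"))
  calls |>
    dplyr::count(.data$call_type, .data$bucket, .drop = FALSE) |>
    tidyr::pivot_wider(names_from = "bucket", values_from = "n",
                       values_fill = 0L) |>
    dplyr::mutate(n = .data$in_proximity + .data$within_1s + .data$outside) |>
    dplyr::filter(.data$n > 0) |>
    dplyr::transmute(
      call_type = .data$call_type, n = .data$n,
      pct_in_proximity = 100 * .data$in_proximity / .data$n,
      pct_within_1s = 100 * .data$within_1s / .data$n,
      pct_outside = 100 * .data$outside / .data$n,
      pct_proximity_incl_buffer = .data$pct_in_proximity + .data$pct_within_1s)
}

#' Call-type shares per behavior
#'
#' For each coded behavior, the percentage of each call type among all calls
#' produced during that behavior (rows sum to 100%). Behaviors during which
#' no call was produced are omitted.
#'
#' @param annotated_calls output of [align_calls()] with a `call_type`
#'   column.
#' @return tibble with `behavior`, `n` and one `pct_<type>` column per call
#'   type.
#' @export
behavior_shares <- function(annotated_calls) {
  stopifnot(all(c("behavior", "call_type") %in% names(annotated_calls)))
  annotated_calls |>
    dplyr::count(.data$behavior, .data$call_type) |>
    dplyr::group_by(.data$behavior) |>
    dplyr::mutate(total = sum(.data$n), pct = 100 * .data$n / .data$total) |>
    dplyr::ungroup() |>
    tidyr::pivot_wider(id_cols = c("behavior", "total"),
                       names_from = "call_type", values_from = "pct",
                       names_prefix = "pct_", values_fill = 0) |>
    dplyr::rename(n = "total")
}

#' Call rates per experiment and call type
#'
#' Rate = number of calls divided by the duration of the phase in minutes
#' (N/min). Every experiment x call-type combination is reported; zero
#' counts give rate 0.
#'
#' @param calls tibble with `experiment_id`, `call_type` and a `phase`
#'   column (or all calls assumed in `phase`).
#' @param experiments dyad table with `experiment_id`, factor columns, and
#'   `<phase>_min` duration columns.
#' @param phase `"open_door"` or `"closed_door"`.
#' @return tibble with the dyad factors and `call_type`, `n`, `rate_per_min`.
#' @export
call_rates <- function(calls, experiments, phase = "open_door") {
  dur_col <- paste0(phase, "_min")
  if (!dur_col %in% names(experiments)) {
    stop("experiments table lacks a ", dur_col, " column")
  }
  if (any(experiments[[dur_col]] <= 0)) {
    stop("phase durations must be positive")
  }
  if ("phase" %in% names(calls)) calls <- calls[calls$phase == phase, ]
  types <- if (is.factor(calls$call_type)) levels(calls$call_type)
           else sort(unique(calls$call_type))
  counts <- calls |>
    dplyr::count(.data$experiment_id, .data$call_type, name = "n")
  grid <- tidyr::expand_grid(experiment_id = experiments$experiment_id,
                             call_type = types)
  grid |>
    dplyr::left_join(counts, by = c("experiment_id", "call_type")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L)) |>
    dplyr::left_join(experiments, by = "experiment_id") |>
    dplyr::mutate(rate_per_min = .data$n / .data[[dur_col]])
}
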