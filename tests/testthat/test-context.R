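# Behavioral-context attribution, shares, and call rates.

events_fixture <- function() {
  tibble::tibble(
    experiment_id = "e1",
    category = c("socio_negative", "box", "caravanning", "wire_mesh"),
    onset = c(10, 8, 30, 50),
    offset = c(20, 25, 40, 60))
}

test_that("calls take the highest-priority containing behavior", {
  calls <- tibble::tibble(
    experiment_id = "e1",
    onset = c(15, 22, 35, 45, 55),
    call_type = factor("scream", levels = CALL_TYPES <- c(
      "scream", "screech", "screech_scream", "chirp")))
  out <- align_calls(calls, events_fixture())
  expect_equal(out$behavior,
               c("socio_negative",              # inside socio_negative & box
                 "box",                         # box only
                 "caravanning",
                 "no_physical_interaction",     # between events
                 "wire_mesh"))
  bad <- events_fixture()
  bad$category[1] <- "grooming"
  expect_error(align_calls(calls, bad), "grooming")
})

test_that("proximity buckets partition the calls per type", {
  prox <- tibble::tibble(experiment_id = "e1", onset = 10, offset = 20)
  calls <- tibble::tibble(
    experiment_id = "e1",
    onset = c(12, 15, 9.5, 20.4, 30),
    call_type = factor(c("scream", "scream", "scream", "scream", "chirp"),
                       levels = c("scream", "screech", "screech_scream",
                                  "chirp")))
  sh <- proximity_shares(calls, prox)
  scream <- sh[sh$call_type == "scream", ]
  expect_equal(scream$pct_in_proximity, 50)     # 2 of 4
  expect_equal(scream$pct_within_1s, 50)        # 0.5 s before, 0.4 s after
  expect_equal(scream$pct_outside, 0)
  chirp <- sh[sh$call_type == "chirp", ]
  expect_equal(chirp$pct_outside, 100)
  sums <- sh$pct_in_proximity + sh$pct_within_1s + sh$pct_outside
  expect_equal(sums, rep(100, nrow(sh)), tolerance = 1e-9)

  all_in <- proximity_shares(calls[1:2, ], prox)
  expect_equal(all_in$pct_in_proximity, 100)
})

test_that("behavior shares are per-behavior percentages summing to 100", {
  ann <- tibble::tibble(
    behavior = c(rep("socio_negative", 4), rep("caravanning", 2)),
    call_type = factor(c("scream", "scream", "scream", "chirp",
                         "chirp", "chirp"),
                       levels = c("scream", "screech", "screech_scream",
                                  "chirp")))
  sh <- behavior_shares(ann)
  sn <- sh[sh$behavior == "socio_negative", ]
  expect_equal(sn$pct_scream, 75)
  expect_equal(sn$pct_chirp, 25)
  car <- sh[sh$behavior == "caravanning", ]
  expect_equal(car$pct_chirp, 100)
  expect_false("avoidance" %in% sh$behavior)     # zero-call rows omitted
  pct_cols <- grep("^pct_", names(sh))
  expect_equal(rowSums(sh[, pct_cols]), rep(100, nrow(sh)),
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("call rates are counts per minute with explicit zeros", {
  experiments <- tibble::tibble(experiment_id = c("e1", "e2"),
                                open_door_min = 15)
  calls <- tibble::tibble(
    experiment_id = rep("e1", 30),
    call_type = factor("scream", levels = c("scream", "chirp")),
    phase = "open_door")
  rates <- call_rates(calls, experiments)
  expect_equal(rates$rate_per_min[rates$experiment_id == "e1" &
                                    rates$call_type == "scream"], 2.0)
  expect_equal(rates$rate_per_min[rates$experiment_id == "e2" &
                                    rates$call_type == "scream"], 0.0)
  expect_equal(nrow(rates), 4)                  # full grid
  experiments$open_door_min <- 0
  expect_error(call_rates(calls, experiments), "positive")
})
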