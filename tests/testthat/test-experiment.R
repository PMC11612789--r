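# Synthetic study generator: bookkeeping, determinism, placement rules,
# artifact round-trips.

test_that("ground-truth bookkeeping matches the requested configuration", {
  plan <- small_plan()
  tt <- plan$ground_truth
  cfg <- plan$config
  expect_equal(nrow(tt), sum(cfg$n_calls) + cfg$n_closed_calls)
  counts <- table(tt$true_type[tt$phase == "open_door"])
  expect_equal(as.vector(counts[names(cfg$n_calls)]),
               unname(cfg$n_calls))
  expect_true(all(tt$offset > tt$onset))
  # the true voiced fraction follows the synthesis rule
  expect_equal(tt$true_voiced_fraction, 100 * tt$tonal_fraction)
  expect_true(all(tt$true_voiced_fraction[tt$true_type == "scream"] == 100))
  expect_true(all(tt$true_voiced_fraction[tt$true_type == "screech"] == 0))
})

test_that("same seed reproduces the plan, different seeds differ", {
  a <- generate_experiment(small_config(), seed = 11)
  b <- generate_experiment(small_config(), seed = 11)
  c <- generate_experiment(small_config(), seed = 12)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_identical(a$behavior_events, b$behavior_events)
  expect_false(identical(a$ground_truth$onset, c$ground_truth$onset))
  # rendering is deterministic too
  ra <- render_recording(a, a$dyads$experiment_id[1])
  rb <- render_recording(b, b$dyads$experiment_id[1])
  expect_identical(ra$samples, rb$samples)
})

test_that("calls are placed in the intended behavioral contexts without overlap", {
  plan <- small_plan()
  tt <- plan$ground_truth[plan$ground_truth$phase == "open_door", ]
  expect_true(all(tt$context_label[tt$true_type == "chirp"] == "caravanning"))
  expect_true(all(tt$context_label[tt$true_type != "chirp"] %in%
                    c("socio_negative", "avoidance")))
  expect_true(all(plan$behavior_events$category %in% ethogram_categories()))
  for (id in unique(tt$experiment_id)) {
    d <- tt[tt$experiment_id == id, ]
    d <- d[order(d$onset), ]
    expect_true(all(d$onset[-1] >= utils::head(d$offset, -1)))
  }
})

test_that("an infeasible request is rejected with an explicit error", {
  cfg <- experiment_config(
    n_calls = c(scream = 400, screech = 400, screech_scream = 200,
                chirp = 200),
    n_experiments = 2,
    phase_min = c(closed_door = 0.1, open_door = 0.4))
  expect_error(generate_experiment(cfg, seed = 1), "exceed available")
})

test_that("written artifacts round-trip (WAV, CSV, TextGrid)", {
  dir <- withr::local_tempdir()
  plan <- generate_experiment(small_config(), seed = 5, dir = dir)
  expect_true(file.exists(file.path(dir, "ground_truth.csv")))
  expect_true(file.exists(file.path(dir, "dyads.csv")))
  id <- plan$dyads$experiment_id[1]

  wav <- read_wav(file.path(dir, paste0(id, ".wav")))
  rec <- render_recording(plan, id)
  expect_equal(wav$sample_rate, rec$sample_rate)
  expect_equal(length(wav$samples), length(rec$samples))
  expect_lt(max(abs(wav$samples - rec$samples)), 1 / 32767)  # 16-bit rounding

  tg <- read_annotations(file.path(dir, paste0(id, "_behavior.TextGrid")),
                         experiment_id = id)
  ev <- plan$behavior_events[plan$behavior_events$experiment_id == id &
                               plan$behavior_events$tier == "interaction", ]
  expect_equal(nrow(tg), nrow(ev))
  expect_equal(tg$onset, ev$onset, tolerance = 1e-5)
  expect_equal(tg$category, ev$category)
})
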