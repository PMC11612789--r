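# TextGrid and CSV annotation round-trips.

test_that("long TextGrids round-trip behavior events", {
  ev <- tibble::tibble(
    category = c("socio_negative", "caravanning", "avoidance"),
    onset = c(1.5, 4.0, 9.25),
    offset = c(3.0, 8.5, 12.0))
  path <- withr::local_tempfile(fileext = ".TextGrid")
  write_textgrid(ev, path, xmax = 15)
  tg <- read_textgrid(path)
  filled <- tg[nzchar(tg$label), ]
  expect_equal(nrow(filled), 3)
  expect_equal(filled$label, ev$category)
  expect_equal(filled$onset, ev$onset, tolerance = 1e-6)
  expect_equal(filled$offset, ev$offset, tolerance = 1e-6)
  # the tier tiles [0, xmax]
  expect_equal(min(tg$onset), 0)
  expect_equal(max(tg$offset), 15)
})

test_that("short-dialect TextGrids parse to the same events", {
  short <- c('File type = "ooTextFile"', 'Object class = "TextGrid"', "",
             "0", "15", "<exists>", "1", '"IntervalTier"', '"behavior"',
             "0", "15", "3",
             "0", "2", '""',
             "2", "5", '"caravanning"',
             "5", "15", '"socio_negative"')
  path <- withr::local_tempfile(fileext = ".TextGrid")
  writeLines(short, path)
  tg <- read_textgrid(path)
  expect_equal(tg$label, c("", "caravanning", "socio_negative"))
  expect_equal(tg$onset, c(0, 2, 5))
})

test_that("CSV and TextGrid encodings produce identical event lists", {
  ev <- tibble::tibble(
    experiment_id = "e1",
    category = c("caravanning", "socio_negative"),
    onset = c(2, 5), offset = c(4, 9))
  tg_path <- withr::local_tempfile(fileext = ".TextGrid")
  csv_path <- withr::local_tempfile(fileext = ".csv")
  write_textgrid(ev, tg_path, xmax = 10)
  readr::write_csv(ev, csv_path)
  from_tg <- read_annotations(tg_path, experiment_id = "e1")
  from_csv <- read_annotations(csv_path)
  expect_equal(from_tg$category, from_csv$category)
  expect_equal(from_tg$onset, from_csv$onset, tolerance = 1e-6)
  expect_equal(from_tg$offset, from_csv$offset, tolerance = 1e-6)
})

test_that("unknown categories and malformed files are rejected with location", {
  ev <- tibble::tibble(category = c("caravanning", "grooming"),
                       onset = c(0, 5), offset = c(4, 9))
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(ev, path)
  expect_error(read_annotations(path), "grooming")
  expect_error(read_annotations(path), "2")

  bad <- withr::local_tempfile(fileext = ".TextGrid")
  writeLines(c("not a textgrid"), bad)
  expect_error(read_textgrid(bad), "malformed")
  expect_error(read_textgrid("does-not-exist.TextGrid"), "not found")
})
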