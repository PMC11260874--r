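test_that("well-formed rows ingest one visit per row, canonically sorted", {
  rows <- rbind(
    csv_row(individual = "b", time = "12:00:00", station = 2),
    csv_row(individual = "a", time = "10:30:00", station = 1),
    csv_row(individual = "a", time = "09:15:00", station = 3)
  )
  path <- tempfile(fileext = ".csv")
  utils::write.csv(rows, path, row.names = FALSE)
  d <- parse_annotations(path, stations = 1:3)
  expect_s3_class(d, "forage_dataset")
  expect_equal(n_visits(d), 3L)
  expect_equal(d$visits$individual, c("a", "a", "b"))
  expect_equal(d$visits$time_min, c(9 * 60 + 15, 10 * 60 + 30, 12 * 60))
  rep <- parse_report(d)
  expect_equal(rep$n_rows, 3L)
  expect_equal(rep$n_records, 3L)
})

test_that("rows outside the window or with bad fields are dropped and counted", {
  rows <- rbind(
    csv_row(individual = "a", time = "07:30:00"),   # before 08:00
    csv_row(individual = "a", time = "10:00:00"),
    csv_row(individual = "a", time = "not-a-time"),
    csv_row(individual = "a", time = "11:00:00", station = 99),
    csv_row(individual = "a", time = "10:00:00")    # exact duplicate
  )
  path <- tempfile(fileext = ".csv")
  utils::write.csv(rows, path, row.names = FALSE)
  d <- parse_annotations(path, stations = 1:5)
  rep <- parse_report(d)
  expect_equal(n_visits(d), 1L)
  expect_equal(rep$n_dropped_outside_window, 1L)
  expect_equal(rep$n_dropped_bad_timestamp, 1L)
  expect_equal(rep$n_dropped_unknown_station, 1L)
  expect_equal(rep$n_deduplicated, 1L)
  # conservation: drops reconcile exactly with input rows
  expect_equal(rep$n_rows - rep$n_records,
               rep$n_dropped_outside_window + rep$n_dropped_bad_timestamp +
                 rep$n_dropped_unknown_station + rep$n_deduplicated)
})

test_that("schema errors name the missing column; empty files error", {
  rows <- csv_row()
  rows$individual <- NULL
  path <- tempfile(fileext = ".csv")
  utils::write.csv(rows, path, row.names = FALSE)
  expect_error(parse_annotations(path), "individual")

  empty <- csv_row()[0, ]
  path2 <- tempfile(fileext = ".csv")
  utils::write.csv(empty, path2, row.names = FALSE)
  expect_error(parse_annotations(path2), "no records")
})

test_that("a foreign export parses through a custom schema mapping", {
  rows <- data.frame(Datum = "2022-11-07", Zeit = "10:00:00", Ort = 2,
                     Art = "H. sara", Tier = "x1", Geschlecht = "w")
  path <- tempfile(fileext = ".csv")
  utils::write.csv(rows, path, row.names = FALSE)
  d <- parse_annotations(path, schema = c(
    date = "Datum", time = "Zeit", station = "Ort", species = "Art",
    individual = "Tier", sex = "Geschlecht"), stations = 1:4)
  expect_equal(n_visits(d), 1L)
  expect_equal(d$visits$station, 2L)
  expect_equal(d$visits$sex, "unknown")  # unmapped sex code
})

test_that("filter_min_visits removes sparse individuals, is idempotent, and conserves records", {
  d <- make_dataset(individual = c("a", "a", "b", "c", "c", "c"),
                    station = c(1, 2, 1, 3, 1, 2),
                    time_min = c(500, 520, 530, 540, 560, 580),
                    stations = 1:5)
  f <- filter_min_visits(d, 2)
  expect_setequal(unique(f$visits$individual), c("a", "c"))
  expect_equal(attr(f, "removed_individuals"), "b")
  expect_equal(n_visits(d) - n_visits(f), 1L)

  f2 <- filter_min_visits(f, 2)
  expect_equal(f2$visits, f$visits)

  expect_equal(filter_min_visits(d, 1)$visits, d$visits)

  expect_warning(empty <- filter_min_visits(d, 10), "empty")
  expect_equal(n_visits(empty), 0L)
})

test_that("datasets round-trip through the annotation dialect", {
  set.seed(7)
  sim <- simulate_dataset(sim_config(
    n_days = 3, groups = data.frame(species = c("H. erato", "D. iulia"),
                                    n_female = c(3L, 2L),
                                    n_male = c(3L, 2L)),
    p_det = 1, p_miss = 0, trial = NA_character_, seed = 11))
  d <- sim$dataset
  path <- tempfile(fileext = ".csv")
  write_annotations(d, path)
  d2 <- parse_annotations(path, stations = d$stations, window = d$window)
  for (col in c("individual", "species", "sex", "station", "date",
                "time_min")) {
    expect_equal(d2$visits[[col]], d$visits[[col]], info = col)
  }
  # a second write of the re-parsed data is byte-identical (canonical form)
  path2 <- tempfile(fileext = ".csv")
  write_annotations(d2, path2)
  expect_identical(readLines(path2), readLines(path))
})

test_that("empty and single-record datasets still write valid files", {
  d1 <- make_dataset("a", 1, 500, stations = 1:3)
  p1 <- tempfile(fileext = ".csv")
  write_annotations(d1, p1)
  expect_length(readLines(p1), 2L)

  d0 <- forage_dataset(d1$visits[0, ], stations = 1:3)
  p0 <- tempfile(fileext = ".csv")
  write_annotations(d0, p0)
  expect_length(readLines(p0), 1L)  # header only
})

test_that("detection_summary counts marked vs detected with one-decimal percent", {
  roster <- data.frame(
    individual = c("a", "b", "c", "d", "e"),
    species = c("H. sara", "H. sara", "H. sara", "D. iulia", "D. iulia"))
  d <- make_dataset(individual = c("a", "a", "b", "d"),
                    station = c(1, 2, 1, 3),
                    time_min = c(500, 510, 520, 530),
                    species = c("H. sara", "H. sara", "H. sara", "D. iulia"),
                    stations = 1:5)
  d$roster <- roster
  ds <- detection_summary(d)
  sara <- ds[ds$species == "H. sara", ]
  expect_equal(sara$marked, 3L)
  expect_equal(sara$detected, 2L)
  expect_equal(sara$percent_detected, 66.7)
  expect_equal(sara$n_videos, 3L)
  tot <- ds[ds$species == "Total", ]
  expect_equal(tot$detected, 3L)
  expect_equal(tot$percent_detected, 60)

  # nothing detected -> 0.0%
  d0 <- forage_dataset(d$visits[0, ], stations = 1:5)
  ds0 <- detection_summary(d0, roster)
  expect_true(all(ds0$percent_detected == 0))

  # detected individual missing from the roster is a consistency error
  expect_error(detection_summary(d, roster[roster$individual != "a", ]),
               "a")
})
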