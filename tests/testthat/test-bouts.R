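test_that("gap and station rules segment toy streams as defined", {
  # same station, gaps 5 and 7 min -> one bout of 3 visits, duration 12
  d1 <- make_dataset("a", c(2, 2, 2), c(600, 605, 612), stations = 1:5)
  b1 <- segment_bouts(d1, 20)
  expect_equal(nrow(b1), 1L)
  expect_equal(b1$n_visits, 3L)
  expect_equal(b1$duration, 12)
  expect_equal(b1$mean_gap, 6)

  # a 25-min gap exceeds the threshold -> two bouts
  d2 <- make_dataset("a", c(2, 2), c(600, 625), stations = 1:5)
  expect_equal(nrow(segment_bouts(d2, 20)), 2L)

  # a station switch breaks the bout even within the threshold
  d3 <- make_dataset("a", c(1, 2), c(600, 605), stations = 1:5)
  b3 <- segment_bouts(d3, 20)
  expect_equal(nrow(b3), 2L)
  expect_equal(b3$duration, c(0, 0))  # single-visit bouts have duration 0

  # a day boundary breaks the bout
  d4 <- make_dataset("a", c(1, 1), c(600, 605),
                     date = as.Date(c("2022-11-07", "2022-11-08")),
                     stations = 1:5)
  expect_equal(nrow(segment_bouts(d4, 20)), 2L)
})

test_that("bouts partition the visit set and are monotone in the threshold", {
  sim <- simulate_dataset(sim_config(
    groups = data.frame(species = "H. erato", n_female = 8L, n_male = 8L),
    n_days = 5, seed = 41))
  d <- sim$dataset
  b20 <- segment_bouts(d, 20)
  expect_equal(sum(b20$n_visits), n_visits(d))
  vb <- attr(b20, "visit_bout")
  expect_length(vb, n_visits(d))
  expect_false(anyNA(vb))

  # raising the threshold never increases the number of bouts
  thresholds <- c(0, 5, 10, 20, 40, Inf)
  n_bouts <- vapply(thresholds,
                    function(th) nrow(segment_bouts(d, th)), numeric(1))
  expect_true(all(diff(n_bouts) <= 0))

  # threshold 0: every (distinct-time) visit is its own bout
  expect_equal(n_bouts[1], n_visits(d))

  # threshold Inf with one station: one bout per individual-day-station run
  one <- d$visits[d$visits$station == d$visits$station[1] &
                    d$visits$individual == d$visits$individual[1], ]
  if (nrow(one) >= 2) {
    dd <- forage_dataset(one, stations = d$stations)
    binf <- segment_bouts(dd, Inf)
    expect_equal(nrow(binf), length(unique(paste(one$individual, one$date))))
  }
})

test_that("bout indices count each individual's bouts cumulatively in time order", {
  d <- make_dataset("a", c(1, 1, 2, 1), c(600, 605, 700, 800),
                    date = as.Date(c("2022-11-07", "2022-11-07",
                                     "2022-11-07", "2022-11-08")),
                    stations = 1:5)
  b <- segment_bouts(d, 20)
  expect_equal(b$bout_index, 1:3)
  expect_true(all(diff(order(b$date, b$start)) > 0))
})

test_that("bout statistics aggregate duration, visits, and pooled intervals", {
  d <- make_dataset("a",
                    station = c(1, 1, 1, 2, 2),
                    time_min = c(600, 605, 610, 700, 730),
                    stations = 1:5)
  # bout 1: 3 visits, duration 10, gaps (5, 5); bout 2 splits at gap 30
  b <- segment_bouts(d, 20)
  expect_equal(nrow(b), 3L)
  st <- bout_statistics(b, by = "species")
  expect_equal(st$mean_duration, mean(c(10, 0, 0)))
  expect_equal(st$mean_visits, mean(c(3, 1, 1)))
  expect_equal(st$mean_interval, 5)
  st2 <- bout_statistics(b, by = "species", camera_hours = 2)
  expect_equal(st2$bouts_per_hour, 1.5)

  # durations 10 and 30 -> mean 20
  d2 <- make_dataset("a", c(1, 1, 1, 1, 1),
                     c(600, 610, 700, 715, 730), stations = 1:5)
  st3 <- bout_statistics(segment_bouts(d2, 20), by = "species")
  expect_equal(st3$mean_duration, 20)

  # single-visit bouts only -> interval mean is NA
  d3 <- make_dataset("a", c(1, 2, 1), c(600, 700, 800), stations = 1:5)
  expect_true(is.na(bout_statistics(segment_bouts(d3, 20))$mean_interval))
})

test_that("simulated bout composition is recovered within Monte-Carlo error", {
  # nu = 10 extra visits, short gaps, clean separation, perfect detection
  sim <- simulate_dataset(sim_config(
    groups = data.frame(species = "H. erato", n_female = 15L, n_male = 15L),
    n_days = 6, bouts_per_day = 1.5, bout_size = 10, gap_mean = 3,
    peak = 620, sd_activity = 50, min_bout_separation = 90,
    p_det = 1, p_miss = 0, preference = list(mode = "uniform"), seed = 42))
  b <- segment_bouts(sim$dataset, 20)
  expect_lt(abs(mean(b$n_visits) - 11) / 11, 0.08)
  st <- bout_statistics(b)
  expect_lt(abs(st$mean_interval - 3) / 3, 0.15)
})

test_that("flowers_per_day counts distinct stations per individual-day", {
  d <- make_dataset(c("a", "a", "a", "b"),
                    station = c(1, 1, 3, 2),
                    time_min = c(600, 610, 620, 600),
                    date = as.Date(c("2022-11-07", "2022-11-07",
                                     "2022-11-07", "2022-11-08")),
                    stations = 1:5)
  fpd <- flowers_per_day(d)
  expect_equal(fpd$n_stations[fpd$individual == "a"], 2L)
  expect_equal(fpd$n_stations[fpd$individual == "b"], 1L)
  expect_equal(nrow(fpd), 2L)  # days without visits are absent

  sim <- simulate_dataset(sim_config(
    groups = data.frame(species = "H. sara", n_female = 20L, n_male = 20L),
    n_days = 4, preference = list(mode = "fidelity", alpha = 1e-9),
    seed = 43))
  expect_true(all(flowers_per_day(sim$dataset)$n_stations == 1L))
})

test_that("bout_trend reports the Pearson correlation with sane degenerate handling", {
  mk_bouts <- function(durations) {
    # one individual, one station, one bout per day with set durations
    n <- length(durations)
    times <- unlist(lapply(durations, function(dur) c(600, 600 + dur)))
    d <- make_dataset("a", rep(1, 2 * n), times,
                      date = rep(as.Date("2022-11-07") + seq_len(n), each = 2),
                      stations = 1:5)
    segment_bouts(d, 20)
  }
  expect_equal(bout_trend(mk_bouts(c(1, 5, 9, 13)))$correlation, 1)
  expect_warning(r0 <- bout_trend(mk_bouts(c(4, 4, 4, 4)))$correlation,
                 "variance")
  expect_true(is.na(r0))
  expect_warning(r1 <- bout_trend(mk_bouts(c(1, 2)))$correlation,
                 "fewer than 3")
  expect_true(is.na(r1))

  # synthetic drift: durations grow with bout index -> positive correlation
  set.seed(44)
  b <- mk_bouts(pmin(19, pmax(0.5, 2 + 0.8 * (1:20) +
                                stats::rnorm(20, 0, 2))))
  expect_gt(bout_trend(b)$correlation, 0)
})

test_that("segmentation recovers ground-truth bouts exactly under clean conditions", {
  sim <- simulate_dataset(sim_config(
    groups = data.frame(species = c("H. erato", "D. iulia"),
                        n_female = c(8L, 8L), n_male = c(8L, 8L)),
    n_days = 5, bouts_per_day = 1.5, bout_size = 3, gap_mean = 5,
    min_bout_separation = 120, peak = 640, sd_activity = 70,
    p_det = 1, p_miss = 0, seed = 45))
  b <- segment_bouts(sim$dataset, 20)
  expect_equal(ari(attr(b, "visit_bout"), truth_bout_labels(sim)), 1)
})
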