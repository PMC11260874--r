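# Shared fixtures and independent oracles for the test suite.

# Quick dataset builder: equal-length vectors of visit fields.
make_dataset <- function(individual, station, time_min,
                         date = as.Date("2022-11-07"),
                         species = "H. erato", sex = "female",
                         stations = NULL, window = c(480, 960)) {
  df <- data.frame(individual = individual, species = species, sex = sex,
                   station = station, date = date, time_min = time_min,
                   stringsAsFactors = FALSE)
  forage_dataset(df, stations = stations, window = window)
}

# Write a small annotation CSV from row vectors; returns the path.
write_fixture_csv <- function(..., path = tempfile(fileext = ".csv")) {
  rows <- data.frame(..., check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(rows, path, row.names = FALSE)
  path
}

csv_row <- function(individual = "id1", species = "H. erato",
                    sex = "female", station = 1, date = "2022-11-07",
                    time = "10:00:00", temperature_C = "30") {
  data.frame(file = "v.mp4", date = date, time = time,
             temperature_C = temperature_C, camera = station,
             station = station, species = species, individual = individual,
             sex = sex, stringsAsFactors = FALSE)
}

# Independent brute-force DET oracle: for every recurrent point, extend its
# diagonal explicitly in both directions and test the resulting maximal
# line length. Deliberately a different algorithm from the package's
# run-length scan.
brute_det <- function(sym, l_min = 3L) {
  n <- length(sym)
  rec <- 0L
  line <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || sym[i] != sym[j]) next
      rec <- rec + 1L
      len <- 1L
      k <- 1L
      while (i - k >= 1L && j - k >= 1L && sym[i - k] == sym[j - k]) {
        len <- len + 1L
        k <- k + 1L
      }
      k <- 1L
      while (i + k <= n && j + k <= n && sym[i + k] == sym[j + k]) {
        len <- len + 1L
        k <- k + 1L
      }
      if (len >= l_min) line <- line + 1L
    }
  }
  if (rec == 0L) 0 else line / rec
}

# Visit-level bout labels from a ground-truth table, aligned to the rows of
# the emitted (detected, canonically sorted) dataset.
truth_bout_labels <- function(sim) {
  tv <- sim$truth$visits[sim$truth$visits$detected, , drop = FALSE]
  key <- function(df) paste(df$individual, df$date, df$time_min, df$station)
  tv$bout_id[match(key(sim$dataset$visits), key(tv))]
}

# Adjusted Rand index between two partitions (labels vectors).
ari <- function(a, b) {
  mclust::adjustedRandIndex(a, b)
}
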