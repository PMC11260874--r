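#' Segment visit streams into feeding bouts
#'
#' A feeding bout is a maximal run of one individual's visits to the same
#' station on the same day with consecutive inter-visit gaps not exceeding
#' `gap_threshold` minutes (20 min by default). Scanning each individual's
#' visits in time order, a visit extends the current bout iff it shares the
#' bout's date and station and follows within the threshold; anything else
#' (station switch, new day, long gap) starts a new bout. Bouts therefore
#' partition the visit set exactly.
#'
#' Single-visit runs count as bouts of one visit with duration 0 (trigger
#' timestamps; the seconds-long recording is negligible on the minutes
#' scale). `bout_index` numbers each individual's bouts 1, 2, ... in time
#' order across the whole dataset.
#'
#' @param d a [forage_dataset()] (canonically sorted by construction).
#' @param gap_threshold maximum within-bout inter-visit gap, minutes.
#' @param min_bout_visits drop bouts with fewer visits from the returned
#'   table (default 1 = keep all); the visit-to-bout assignment attribute
#'   always covers every visit.
#' @return data.frame of class `forage_bouts` with columns `individual`,
#'   `species`, `sex`, `date`, `station`, `start`, `end`, `duration`,
#'   `n_visits`, `mean_gap`, `bout_index`. Attributes: `visit_bout`
#'   (integer bout id per visit row of `d`), `gap_threshold`.
#' @export
segment_bouts <- function(d, gap_threshold = 20, min_bout_visits = 1L) {
  stopifnot(inherits(d, "forage_dataset"), gap_threshold >= 0)
  v <- d$visits
  if (nrow(v) == 0L) {
    out <- data.frame(individual = character(0), species = character(0),
                      sex = character(0), date = as.Date(character(0)),
                      station = integer(0), start = numeric(0),
                      end = numeric(0), duration = numeric(0),
                      n_visits = integer(0), mean_gap = numeric(0),
                      bout_index = integer(0))
    attr(out, "visit_bout") <- integer(0)
    attr(out, "gap_threshold") <- gap_threshold
    class(out) <- c("forage_bouts", "data.frame")
    return(out)
  }
  n <- nrow(v)
  gap <- c(Inf, diff(v$time_min))
  new_bout <- c(TRUE, v$individual[-1] != v$individual[-n] |
                      v$date[-1] != v$date[-n] |
                      v$station[-1] != v$station[-n]) |
              gap > gap_threshold
  bout_id <- cumsum(new_bout)
  starts <- which(new_bout)
  ends <- c(starts[-1] - 1L, n)
  lens <- ends - starts + 1L

  out <- data.frame(
    individual = v$individual[starts], species = v$species[starts],
    sex = v$sex[starts], date = v$date[starts], station = v$station[starts],
    start = v$time_min[starts], end = v$time_min[ends],
    n_visits = lens, stringsAsFactors = FALSE
  )
  out$duration <- out$end - out$start
  out$mean_gap <- ifelse(lens > 1L, out$duration / (lens - 1L), NA_real_)
  # cumulative ordinal per individual, in time order (rows already sorted)
  out$bout_index <- stats::ave(seq_len(nrow(out)), out$individual,
                               FUN = seq_along)
  out <- out[, c("individual", "species", "sex", "date", "station", "start",
                 "end", "duration", "n_visits", "mean_gap", "bout_index")]
  if (min_bout_visits > 1L) {
    out <- out[out$n_visits >= min_bout_visits, , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "visit_bout") <- bout_id
  attr(out, "gap_threshold") <- gap_threshold
  class(out) <- c("forage_bouts", "data.frame")
  out
}

#' Summary statistics of feeding bouts
#'
#' Per-group mean bout duration, mean visits per bout, mean intra-bout
#' inter-visit interval (over bouts with at least 2 visits, pooled across
#' all intervals), and optionally bouts per hour of camera time.
#'
#' @param bouts result of [segment_bouts()].
#' @param by grouping columns of the bout table (default `"species"`).
#' @param camera_hours total camera recording time in hours, for the
#'   bouts-per-hour rate; omitted (`NA`) when not given or zero.
#' @return data.frame with columns `group`, `n_bouts`, `mean_duration`,
#'   `mean_visits`, `mean_interval`, `bouts_per_hour`.
#' @export
bout_statistics <- function(bouts, by = "species", camera_hours = NULL) {
  stopifnot(inherits(bouts, "forage_bouts"))
  if (nrow(bouts) == 0L) stop("no bouts to summarise")
  key <- interaction(bouts[by], drop = TRUE, sep = ":")
  out <- do.call(rbind, lapply(levels(key), function(gname) {
    b <- bouts[key == gname, , drop = FALSE]
    multi <- b$n_visits > 1L
    data.frame(
      group = gname, n_bouts = nrow(b),
      mean_duration = mean(b$duration),
      mean_visits = mean(b$n_visits),
      # pooled over intervals: weight each bout's mean gap by its gap count
      mean_interval = if (any(multi)) {
        sum(b$mean_gap[multi] * (b$n_visits[multi] - 1L)) /
          sum(b$n_visits[multi] - 1L)
      } else NA_real_,
      bouts_per_hour = if (!is.null(camera_hours) && camera_hours > 0) {
        nrow(b) / camera_hours
      } else NA_real_,
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Distinct stations visited per individual-day
#'
#' @param d a [forage_dataset()].
#' @return data.frame with columns `individual`, `date`, `n_stations`; one
#'   row per (individual, day) with at least one visit.
#' @export
flowers_per_day <- function(d) {
  stopifnot(inherits(d, "forage_dataset"))
  v <- d$visits
  if (nrow(v) == 0L) {
    return(data.frame(individual = character(0),
                      date = as.Date(character(0)), n_stations = integer(0)))
  }
  agg <- stats::aggregate(station ~ individual + date, data = v,
                          FUN = function(s) length(unique(s)))
  names(agg)[names(agg) == "station"] <- "n_stations"
  agg <- agg[order(agg$individual, agg$date, method = "radix"), ,
             drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Trend of bout duration over successive bouts
#'
#' Pearson correlation between an individual's cumulative bout ordinal
#' (`bout_index`) and bout duration, pooled across the individuals of each
#' group; a positive value means bouts lengthen as the trial progresses.
#'
#' @param bouts result of [segment_bouts()].
#' @param by grouping columns (default `"species"`).
#' @return data.frame with columns `group`, `n_bouts`, `correlation`
#'   (`NA` with a warning for groups with fewer than 3 bouts or zero
#'   variance).
#' @export
bout_trend <- function(bouts, by = "species") {
  stopifnot(inherits(bouts, "forage_bouts"))
  key <- interaction(bouts[by], drop = TRUE, sep = ":")
  out <- do.call(rbind, lapply(levels(key), function(gname) {
    b <- bouts[key == gname, , drop = FALSE]
    r <- if (nrow(b) < 3L) {
      warning("group '", gname, "' has fewer than 3 bouts; ",
              "correlation not computed")
      NA_real_
    } else if (stats::sd(b$duration) == 0 || stats::sd(b$bout_index) == 0) {
      warning("group '", gname, "' has zero variance; correlation is NA")
      NA_real_
    } else {
      stats::cor(b$bout_index, b$duration)
    }
    data.frame(group = gname, n_bouts = nrow(b), correlation = r,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
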