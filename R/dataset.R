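#' Canonical visitation dataset
#'
#' Container for camera-trap visit records of marked individuals at flower
#' stations. One record is one triggered video in which one marked individual
#' was annotated; two individuals in one video are two records. Records are
#' kept in canonical order (individual, date, time), which every downstream
#' stage assumes.
#'
#' @param visits data.frame with columns `individual` (character),
#'   `species` (character), `sex` (one of `"female"`, `"male"`, `"unknown"`),
#'   `station` (integer station label), `date` (`Date`), `time_min` (numeric
#'   minutes since midnight), and optionally `temp_c`, `trial`, `group`.
#' @param stations integer vector of valid station labels. Defaults to the
#'   sorted labels present in `visits`. At least 2 stations are required.
#' @param window numeric length-2 recording window in minutes since midnight;
#'   default `c(480, 960)` (08:00--16:00). All `time_min` must lie inside it.
#' @param roster optional data.frame of released individuals with columns
#'   `individual`, `species` (used by [detection_summary()]).
#'
#' @return An object of class `forage_dataset`: a list with elements
#'   `visits`, `stations`, `window`, `roster`.
#' @seealso [parse_annotations()], [simulate_dataset()]
#' @export
forage_dataset <- function(visits, stations = NULL, window = c(480, 960),
                           roster = NULL) {
  stopifnot(is.data.frame(visits))
  required <- c("individual", "species", "sex", "station", "date", "time_min")
  missing_cols <- setdiff(required, names(visits))
  if (length(missing_cols) > 0L) {
    stop("visits is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!is.numeric(window) || length(window) != 2L || diff(window) < 1) {
    stop("window must be two minute values spanning at least 1 minute")
  }
  for (opt in c("temp_c", "trial", "group")) {
    if (!opt %in% names(visits)) visits[[opt]] <- NA
  }
  visits$individual <- as.character(visits$individual)
  visits$species <- as.character(visits$species)
  visits$sex <- normalize_sex(visits$sex)
  visits$station <- as.integer(visits$station)
  visits$date <- as.Date(visits$date)
  visits$time_min <- as.numeric(visits$time_min)

  if (nrow(visits) > 0L) {
    bad_time <- visits$time_min < window[1] | visits$time_min > window[2]
    if (any(bad_time, na.rm = TRUE)) {
      stop(sum(bad_time), " record(s) outside the recording window [",
           window[1], ", ", window[2], "] minutes")
    }
  }
  if (is.null(stations)) {
    stations <- sort(unique(visits$station))
  }
  stations <- sort(unique(as.integer(stations)))
  if (length(stations) < 2L) {
    stop("at least 2 stations are required (got ", length(stations), ")")
  }
  if (nrow(visits) > 0L && !all(visits$station %in% stations)) {
    stop("visits contain station labels outside the station set")
  }
  visits <- canonical_sort(visits)
  rownames(visits) <- NULL
  structure(
    list(visits = visits, stations = stations, window = window,
         roster = roster),
    class = "forage_dataset"
  )
}

# Sort records by (individual, date, time); radix keeps ordering
# locale-independent so pipelines are byte-reproducible.
canonical_sort <- function(visits) {
  visits[order(visits$individual, visits$date, visits$time_min,
               visits$station, method = "radix"), , drop = FALSE]
}

normalize_sex <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep("unknown", length(x))
  out[x %in% c("f", "fem", "female")] <- "female"
  out[x %in% c("m", "male")] <- "male"
  out
}

#' @export
print.forage_dataset <- function(x, ...) {
  v <- x$visits
  cat("<forage_dataset>\n")
  cat("  visits:     ", nrow(v), "\n", sep = "")
  cat("  individuals:", length(unique(v$individual)), "\n")
  cat("  species:    ", length(unique(v$species)), "\n")
  cat("  stations:   ", paste(x$stations, collapse = ", "), "\n")
  cat("  window:     ", sprintf("%s-%s", fmt_hhmm(x$window[1]),
                                fmt_hhmm(x$window[2])), "\n")
  if (nrow(v) > 0L) {
    cat("  dates:      ", paste(range(v$date), collapse = " to "), "\n")
  }
  invisible(x)
}

#' @export
summary.forage_dataset <- function(object, ...) {
  v <- object$visits
  by_sp <- if (nrow(v) > 0L) table(v$species) else table(character(0))
  out <- list(
    n_visits = nrow(v),
    n_individuals = length(unique(v$individual)),
    visits_by_species = by_sp,
    stations = object$stations,
    window = object$window
  )
  class(out) <- "summary.forage_dataset"
  out
}

#' @export
print.summary.forage_dataset <- function(x, ...) {
  cat("Visitation dataset:", x$n_visits, "visits by", x$n_individuals,
      "individuals over", length(x$stations), "stations\n")
  if (length(x$visits_by_species) > 0L) {
    print(x$visits_by_species)
  }
  invisible(x)
}

#' @export
as.data.frame.forage_dataset <- function(x, ...) {
  x$visits
}

#' Number of visit records
#' @param d a [forage_dataset()]
#' @return integer count of records
#' @export
n_visits <- function(d) {
  stopifnot(inherits(d, "forage_dataset"))
  nrow(d$visits)
}

# minutes since midnight -> "HH:MM"
fmt_hhmm <- function(m) {
  m <- round(m)
  sprintf("%02d:%02d", m %/% 60, m %% 60)
}

# minutes since midnight -> "HH:MM:SS" at whole-second precision
fmt_hhmmss <- function(m) {
  s <- round(m * 60)
  sprintf("%02d:%02d:%02d", s %/% 3600, (s %% 3600) %/% 60, s %% 60)
}

# trapezoid integral on an ordered grid
trapz_int <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}
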