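#' Default annotation-table column mapping
#'
#' Maps canonical field names to the column headers of the supported CSV
#' dialect (one row per triggered video: `file,date,time,temperature_C,
#' camera,station,species,individual,sex`). Foreign exports can be ingested
#' by supplying a modified mapping (or a YAML file of the same shape) to
#' [parse_annotations()].
#'
#' @return named character vector, canonical name -> column header.
#' @export
default_schema <- function() {
  c(date = "date", time = "time", station = "station",
    species = "species", individual = "individual", sex = "sex",
    temperature = "temperature_C")
}

# fields that must be present in the mapped file
.mandatory_fields <- c("date", "time", "station", "species", "individual")

#' Parse an annotation table into a canonical dataset
#'
#' Reads a CSV export of video-review annotations (one row per triggered
#' video in which a marked individual was recorded) and returns a validated,
#' canonically sorted [forage_dataset()]. Rows with unparseable timestamps,
#' unknown stations, or times outside the recording window are dropped and
#' counted; exact duplicate rows are removed once. The counts are available
#' via [parse_report()].
#'
#' @param path path to the CSV file.
#' @param schema named character vector mapping canonical field names to the
#'   file's column headers (see [default_schema()]), or the path to a YAML
#'   file containing such a mapping.
#' @param window recording window in minutes since midnight
#'   (default `c(480, 960)`, i.e. 08:00--16:00); records outside it are
#'   dropped, not clamped.
#' @param stations optional integer vector of valid station labels; rows with
#'   other labels are dropped and counted. Defaults to the labels observed.
#' @param trial,group optional labels attached to every record.
#'
#' @return a [forage_dataset()] with a `parse_report` attribute.
#' @export
parse_annotations <- function(path, schema = default_schema(),
                              window = c(480, 960), stations = NULL,
                              trial = NA_character_, group = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.character(schema) && length(schema) == 1L && file.exists(schema)) {
    schema <- unlist(yaml::read_yaml(schema))
  }
  schema <- c(schema, default_schema()[setdiff(names(default_schema()),
                                               names(schema))])
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  missing_cols <- schema[.mandatory_fields][
    !schema[.mandatory_fields] %in% names(raw)]
  if (length(missing_cols) > 0L) {
    stop("annotation file is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(raw) == 0L) stop("annotation file contains no records: ", path)

  n_in <- nrow(raw)
  get <- function(field) {
    col <- schema[[field]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]] else
      rep(NA_character_, n_in)
  }
  date <- suppressWarnings(as.Date(get("date"), format = "%Y-%m-%d"))
  time_min <- parse_hms(get("time"))
  station <- suppressWarnings(as.integer(get("station")))
  temp <- suppressWarnings(as.numeric(get("temperature")))

  df <- data.frame(
    individual = get("individual"), species = get("species"),
    sex = normalize_sex(get("sex")), station = station, date = date,
    time_min = time_min, temp_c = temp,
    trial = trial, group = group, stringsAsFactors = FALSE
  )

  bad_ts <- is.na(df$date) | is.na(df$time_min)
  n_bad_ts <- sum(bad_ts)
  df <- df[!bad_ts, , drop = FALSE]

  if (is.null(stations)) {
    stations <- sort(unique(df$station[!is.na(df$station)]))
  }
  bad_station <- is.na(df$station) | !df$station %in% stations
  n_bad_station <- sum(bad_station)
  df <- df[!bad_station, , drop = FALSE]

  out_window <- df$time_min < window[1] | df$time_min > window[2]
  n_out_window <- sum(out_window)
  df <- df[!out_window, , drop = FALSE]

  key_cols <- c("individual", "species", "sex", "station", "date", "time_min")
  dup <- duplicated(df[key_cols])
  n_dup <- sum(dup)
  df <- df[!dup, , drop = FALSE]

  d <- forage_dataset(df, stations = stations, window = window)
  attr(d, "parse_report") <- list(
    path = path, n_rows = n_in, n_records = nrow(df),
    n_dropped_bad_timestamp = n_bad_ts,
    n_dropped_unknown_station = n_bad_station,
    n_dropped_outside_window = n_out_window,
    n_deduplicated = n_dup
  )
  d
}

#' Retrieve the parse report of a dataset
#'
#' @param d a [forage_dataset()] returned by [parse_annotations()].
#' @return named list of row counts (input rows, kept records, and the
#'   number dropped for each reason), or `NULL` if `d` was not parsed
#'   from a file.
#' @export
parse_report <- function(d) {
  attr(d, "parse_report")
}

# "HH:MM:SS" / "HH:MM" -> minutes since midnight; NA if unparseable.
# Arithmetic is (3600 h + 60 m + s)/60 so whole-second times round-trip
# exactly through fmt_hhmmss().
parse_hms <- function(x) {
  ok <- grepl("^\\s*\\d{1,2}:\\d{2}(:\\d{2})?\\s*$", x)
  out <- rep(NA_real_, length(x))
  if (any(ok)) {
    parts <- strsplit(trimws(x[ok]), ":", fixed = TRUE)
    out[ok] <- vapply(parts, function(p) {
      p <- as.numeric(p)
      if (length(p) == 2L) p <- c(p, 0)
      if (p[1] > 23 || p[2] > 59 || p[3] > 59) return(NA_real_)
      (3600 * p[1] + 60 * p[2] + p[3]) / 60
    }, numeric(1))
  }
  out
}

#' Write a dataset in the annotation CSV dialect
#'
#' Emits the canonical table (`file,date,time,temperature_C,camera,station,
#' species,individual,sex`; ISO dates, HH:MM:SS times). Output round-trips
#' through [parse_annotations()]. The `camera` column repeats the station
#' label (one camera per station) and `file` is a synthesized video name.
#'
#' @param d a [forage_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(d, path) {
  stopifnot(inherits(d, "forage_dataset"))
  v <- d$visits
  out <- data.frame(
    file = if (nrow(v) > 0L) sprintf("video_%06d.mp4", seq_len(nrow(v)))
           else character(0),
    date = format(v$date, "%Y-%m-%d"),
    time = if (nrow(v) > 0L) fmt_hhmmss(v$time_min) else character(0),
    temperature_C = ifelse(is.na(v$temp_c), "", format(v$temp_c,
                                                       trim = TRUE)),
    camera = v$station, station = v$station, species = v$species,
    individual = v$individual, sex = v$sex,
    stringsAsFactors = FALSE, check.names = FALSE
  )
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("could not write annotations to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Drop individuals with too few recorded visits
#'
#' Individuals recorded fewer than `min_visits` times carry too little
#' information for per-individual analyses and are removed (default
#' threshold: 2 visits). The removed identities are attached as the
#' `removed_individuals` attribute.
#'
#' @param d a [forage_dataset()].
#' @param min_visits minimum number of records an individual must have to be
#'   retained; must be >= 1.
#' @return the filtered [forage_dataset()].
#' @export
filter_min_visits <- function(d, min_visits = 2L) {
  stopifnot(inherits(d, "forage_dataset"), min_visits >= 1L)
  v <- d$visits
  counts <- table(v$individual)
  keep_ids <- names(counts)[counts >= min_visits]
  removed <- setdiff(names(counts), keep_ids)
  v <- v[v$individual %in% keep_ids, , drop = FALSE]
  if (nrow(v) == 0L) {
    warning("all individuals fall below min_visits = ", min_visits,
            "; dataset is empty")
  }
  out <- forage_dataset(v, stations = d$stations, window = d$window,
                        roster = d$roster)
  attr(out, "parse_report") <- attr(d, "parse_report")
  attr(out, "removed_individuals") <- removed
  out
}

#' Detection summary against a release roster
#'
#' Tabulates, per species and in total, how many released (marked)
#' individuals were ever detected by the cameras, the detection percentage
#' (one decimal), and the number of videos (records).
#'
#' @param d a [forage_dataset()]; may be empty.
#' @param roster data.frame of released individuals with columns
#'   `individual`, `species`. Defaults to `d$roster`.
#' @return data.frame of class `detection_summary` with columns `species`,
#'   `marked`, `detected`, `percent_detected`, `n_videos`; the final row is
#'   the total.
#' @export
detection_summary <- function(d, roster = d$roster) {
  stopifnot(inherits(d, "forage_dataset"))
  if (is.null(roster) || nrow(roster) == 0L) {
    stop("a non-empty release roster (individual, species) is required")
  }
  stopifnot(all(c("individual", "species") %in% names(roster)))
  roster$individual <- as.character(roster$individual)
  roster$species <- as.character(roster$species)
  if (anyDuplicated(roster$individual)) {
    stop("roster lists duplicate individual id(s)")
  }
  v <- d$visits
  stray <- setdiff(unique(v$individual), roster$individual)
  if (length(stray) > 0L) {
    stop("detected individual(s) absent from the roster: ",
         paste(stray, collapse = ", "))
  }
  species <- unique(roster$species)
  rows <- lapply(species, function(sp) {
    ids <- roster$individual[roster$species == sp]
    det <- unique(v$individual[v$individual %in% ids])
    data.frame(species = sp, marked = length(ids), detected = length(det),
               n_videos = sum(v$individual %in% ids),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(
    species = "Total", marked = sum(out$marked),
    detected = sum(out$detected), n_videos = sum(out$n_videos)
  ))
  out$percent_detected <- round(100 * out$detected / out$marked, 1)
  out <- out[, c("species", "marked", "detected", "percent_detected",
                 "n_videos")]
  class(out) <- c("detection_summary", "data.frame")
  out
}

#' @export
print.detection_summary <- function(x, ...) {
  cat("Detection of marked individuals\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
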