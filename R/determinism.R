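#' Collapse consecutive repeat visits into a station sequence
#'
#' Within a feeding bout an individual triggers many videos at the same
#' station; for sequence analysis those runs are collapsed to a single
#' symbol so bout structure does not masquerade as route repeatability.
#' Chronological order is preserved and no two adjacent symbols are equal
#' afterwards.
#'
#' @param stations ordered vector of station labels (one individual's
#'   visits in time order); at least one visit.
#' @return object of class `station_sequence`: list with `symbols`,
#'   `raw_length`, `collapsed_length`.
#' @export
collapse_runs <- function(stations) {
  stopifnot(length(stations) >= 1L)
  sym <- rle(as.vector(stations))$values
  structure(
    list(symbols = sym, raw_length = length(stations),
         collapsed_length = length(sym)),
    class = "station_sequence"
  )
}

#' @export
print.station_sequence <- function(x, ...) {
  cat("<station_sequence> ", x$raw_length, " visits -> ",
      x$collapsed_length, " symbols: ",
      paste(x$symbols, collapse = " "), "\n", sep = "")
  invisible(x)
}

as_station_sequence <- function(x, collapse = TRUE) {
  if (inherits(x, "station_sequence")) return(x)
  if (collapse) return(collapse_runs(x))
  structure(list(symbols = as.vector(x), raw_length = length(x),
                 collapsed_length = length(x)),
            class = "station_sequence")
}

#' Recurrence matrix of a station sequence
#'
#' Binary matrix with `R[i, j] = 1` iff symbols `i` and `j` are the same
#' station and `i != j` (the trivial main diagonal is excluded). Identity
#' matching on symbols: no embedding, no radius.
#'
#' @param s a `station_sequence` (see [collapse_runs()]) or a plain vector
#'   of station labels (used as-is).
#' @return symmetric 0/1 integer matrix.
#' @export
recurrence_matrix <- function(s) {
  s <- as_station_sequence(s, collapse = FALSE)
  sym <- s$symbols
  if (length(sym) < 2L) {
    stop("sequence too short for a recurrence matrix (need >= 2 symbols)")
  }
  m <- outer(sym, sym, `==`) * 1L
  diag(m) <- 0L
  m
}

#' Determinism (DET) of a station sequence
#'
#' Recurrence-quantification determinism of a symbolic visit sequence: the
#' fraction of recurrent points (off-diagonal matches in the recurrence
#' matrix) that lie on diagonal lines of length at least `l_min`. A diagonal
#' line of length `l` is a maximal run with `symbols[i + k] == symbols[j + k]`
#' for `k = 0..l-1` (`i != j`), i.e. a repeated sub-sequence. DET is 1 when
#' the individual always repeats the same station sequence and 0 when no
#' sub-sequence of length `l_min` ever recurs; a sequence with no recurrent
#' points at all has DET 0 by convention.
#'
#' Consecutive repeat visits are collapsed first by default (see
#' [collapse_runs()]); pass `collapse = FALSE` for a sensitivity analysis on
#' the raw sequence. Sequences shorter than `l_min` after collapsing are
#' returned as exclusion records (`det = NA`).
#'
#' @param x vector of station labels in time order, or a
#'   `station_sequence`.
#' @param l_min minimum diagonal line length (default 3, i.e. recurrent
#'   runs of 3 flowers); must be >= 2.
#' @param collapse collapse consecutive repeats before analysis?
#' @param distinct_in_line if `TRUE`, a qualifying line must additionally
#'   contain at least `l_min` distinct stations (stricter reading of
#'   "3 different flowers"; off by default).
#' @return object of class `det_result`: list with `det`, `l_min`,
#'   `raw_length`, `collapsed_length`, `n_recurrent_points`,
#'   `n_line_points`, `excluded`, `excluded_reason`.
#' @export
det_statistic <- function(x, l_min = 3L, collapse = TRUE,
                          distinct_in_line = FALSE) {
  stopifnot(l_min >= 2L)
  s <- as_station_sequence(x, collapse = collapse)
  sym <- s$symbols
  n <- length(sym)
  base <- list(l_min = as.integer(l_min), raw_length = s$raw_length,
               collapsed_length = s$collapsed_length)
  if (n < l_min) {
    out <- c(base, list(det = NA_real_, n_recurrent_points = NA_integer_,
                        n_line_points = NA_integer_, excluded = TRUE,
                        excluded_reason = sprintf(
                          "sequence length %d < l_min = %d", n, l_min)))
    class(out) <- "det_result"
    return(out)
  }
  n_rec <- 0L
  n_line <- 0L
  for (d in seq_len(n - 1L)) {
    hits <- sym[seq_len(n - d)] == sym[seq_len(n - d) + d]
    n_rec <- n_rec + 2L * sum(hits)      # both triangles of the matrix
    runs <- rle(hits)
    if (!any(runs$values)) next
    run_end <- cumsum(runs$lengths)
    for (r in which(runs$values)) {
      len <- runs$lengths[r]
      if (len < l_min) next
      if (distinct_in_line) {
        i0 <- run_end[r] - len + 1L
        if (length(unique(sym[i0:(i0 + len - 1L)])) < l_min) next
      }
      n_line <- n_line + 2L * len
    }
  }
  out <- c(base, list(
    det = if (n_rec > 0L) n_line / n_rec else 0,
    n_recurrent_points = n_rec, n_line_points = n_line,
    excluded = FALSE, excluded_reason = NA_character_))
  class(out) <- "det_result"
  out
}

#' @export
print.det_result <- function(x, ...) {
  if (x$excluded) {
    cat("DET: excluded (", x$excluded_reason, ")\n", sep = "")
  } else {
    cat(sprintf(
      "DET = %.3f (l_min = %d; %d of %d recurrent points on lines; %d -> %d symbols)\n",
      x$det, x$l_min, x$n_line_points, x$n_recurrent_points,
      x$raw_length, x$collapsed_length))
  }
  invisible(x)
}

#' Determinism of every individual's visit sequence
#'
#' Builds each individual's chronological station sequence, collapses
#' within-bout repeats (by default), and computes [det_statistic()].
#' Individuals whose collapsed sequence is shorter than `l_min` -- notably
#' single-station individuals, whose sequence collapses to one symbol --
#' are excluded with a reason.
#'
#' @param d a [forage_dataset()].
#' @inheritParams det_statistic
#' @return data.frame with columns `individual`, `species`, `raw_length`,
#'   `collapsed_length`, `n_recurrent_points`, `det`, `excluded_reason`.
#' @export
det_by_individual <- function(d, l_min = 3L, collapse = TRUE,
                              distinct_in_line = FALSE) {
  stopifnot(inherits(d, "forage_dataset"))
  v <- d$visits
  meta <- unique(v[, c("individual", "species")])
  ids <- sort(unique(v$individual), method = "radix")
  out <- do.call(rbind, lapply(ids, function(id) {
    res <- det_statistic(v$station[v$individual == id], l_min = l_min,
                         collapse = collapse,
                         distinct_in_line = distinct_in_line)
    data.frame(
      individual = id,
      species = meta$species[match(id, meta$individual)],
      raw_length = res$raw_length, collapsed_length = res$collapsed_length,
      n_recurrent_points = res$n_recurrent_points, det = res$det,
      excluded_reason = res$excluded_reason, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
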