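#' Daily activity density from visit times
#'
#' Gaussian kernel density estimate of the distribution of visit times over
#' the day, with Silverman's rule-of-thumb bandwidth, evaluated on a uniform
#' grid spanning the recording window padded on each side (padding stops the
#' kernel mass of early/late visits being clipped at the window edge). The
#' estimate is renormalised so its trapezoid integral over the grid is 1,
#' making pairwise overlap coefficients well defined.
#'
#' @param times numeric vector of visit times, minutes since midnight; at
#'   least 2 distinct values.
#' @param grid_size number of evaluation points (default 512).
#' @param pad grid padding beyond the window, minutes (default 60).
#' @param window recording window, minutes since midnight.
#' @param group optional label carried into results.
#' @return object of class `activity_density`: list with `grid`, `density`,
#'   `bandwidth`, `n`, `group`.
#' @export
estimate_activity_density <- function(times, grid_size = 512L, pad = 60,
                                      window = c(480, 960), group = NA) {
  times <- as.numeric(times)
  if (length(times) < 2L) {
    stop("at least 2 visit times are needed to estimate an activity density")
  }
  if (stats::sd(times) == 0) {
    stop("all visit times are identical: bandwidth is degenerate")
  }
  kde <- stats::density(times, bw = "nrd0", kernel = "gaussian",
                        from = window[1] - pad, to = window[2] + pad,
                        n = grid_size)
  activity_density(kde$x, kde$y, bandwidth = kde$bw, n = length(times),
                   group = group)
}

#' Construct an activity density on an explicit grid
#'
#' Wraps an already-evaluated (possibly analytic) density so it can be fed
#' to [overlap_coefficient()]; values are renormalised to integrate to 1 by
#' the trapezoid rule on the grid.
#'
#' @param grid increasing numeric evaluation times (minutes).
#' @param density nonnegative density values on `grid`.
#' @param bandwidth smoothing bandwidth in minutes, if any.
#' @param n sample size behind the estimate, if any.
#' @param group optional label.
#' @return object of class `activity_density`.
#' @export
activity_density <- function(grid, density, bandwidth = NA_real_,
                             n = NA_integer_, group = NA) {
  stopifnot(length(grid) == length(density), length(grid) >= 2L,
            !is.unsorted(grid, strictly = TRUE))
  if (any(density < 0)) stop("density values must be nonnegative")
  total <- trapz_int(grid, density)
  if (total <= 0) stop("density integrates to zero on the grid")
  structure(
    list(grid = as.numeric(grid), density = as.numeric(density) / total,
         bandwidth = bandwidth, n = n, group = group),
    class = "activity_density"
  )
}

#' @export
print.activity_density <- function(x, ...) {
  cat("<activity_density>",
      if (!is.na(x$group)) paste0(" [", x$group, "]"), "\n", sep = "")
  cat("  n = ", x$n, ", bandwidth = ",
      if (is.na(x$bandwidth)) "NA" else sprintf("%.1f min", x$bandwidth),
      ", grid ", length(x$grid), " points on [",
      fmt_hhmm(min(x$grid)), ", ", fmt_hhmm(max(x$grid)), "]\n", sep = "")
  mode_t <- x$grid[which.max(x$density)]
  cat("  mode at ", fmt_hhmm(mode_t), "\n", sep = "")
  invisible(x)
}

#' Coefficient of temporal overlap between two activity densities
#'
#' The overlap coefficient Delta is the integral of the pointwise minimum of
#' two probability densities: 1 for identical activity schedules, 0 for
#' disjoint ones. Both densities must have been evaluated on the same grid.
#'
#' @param f,g objects of class `activity_density` sharing an identical grid.
#' @return object of class `overlap_result`: list with `group_a`, `group_b`,
#'   `delta` (in `[0, 1]`), `n_a`, `n_b`.
#' @export
overlap_coefficient <- function(f, g) {
  stopifnot(inherits(f, "activity_density"), inherits(g, "activity_density"))
  if (length(f$grid) != length(g$grid) ||
      !isTRUE(all.equal(f$grid, g$grid, tolerance = 1e-9))) {
    stop("densities were evaluated on different grids; ",
         "re-estimate them on a common grid")
  }
  delta <- trapz_int(f$grid, pmin(f$density, g$density))
  delta <- min(max(delta, 0), 1)
  structure(
    list(group_a = f$group, group_b = g$group, delta = delta,
         n_a = f$n, n_b = g$n),
    class = "overlap_result"
  )
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("Overlap Delta(%s, %s) = %.3f  (n = %s, %s)\n",
              x$group_a, x$group_b, x$delta, x$n_a, x$n_b))
  invisible(x)
}

#' Pairwise activity-overlap matrix
#'
#' Estimates one activity density per group (on a shared grid) and returns
#' the symmetric matrix of pairwise overlap coefficients. Groups with fewer
#' than 2 visits, or without time variation, are skipped with a warning.
#'
#' @param d a [forage_dataset()].
#' @param by grouping columns of the visit table (default `"species"`).
#' @inheritParams estimate_activity_density
#' @return numeric matrix of Delta values with unit diagonal; attribute
#'   `densities` holds the per-group `activity_density` objects.
#' @export
overlap_matrix <- function(d, by = "species", grid_size = 512L, pad = 60) {
  stopifnot(inherits(d, "forage_dataset"))
  v <- d$visits
  key <- interaction(v[by], drop = TRUE, sep = ":")
  groups <- levels(key)
  dens <- list()
  for (gname in groups) {
    t_g <- v$time_min[key == gname]
    dens[[gname]] <- tryCatch(
      estimate_activity_density(t_g, grid_size = grid_size, pad = pad,
                                window = d$window, group = gname),
      error = function(e) {
        warning("skipping group '", gname, "': ", conditionMessage(e))
        NULL
      })
  }
  dens <- Filter(Negate(is.null), dens)
  gs <- names(dens)
  m <- matrix(1, length(gs), length(gs), dimnames = list(gs, gs))
  if (length(gs) >= 2L) {
    for (i in seq_along(gs)[-1]) {
      for (j in seq_len(i - 1L)) {
        m[i, j] <- m[j, i] <- overlap_coefficient(dens[[i]], dens[[j]])$delta
      }
    }
  }
  attr(m, "densities") <- dens
  m
}

#' Mean activity time per group
#'
#' Arithmetic mean and standard error of visit time-of-day per group,
#' reported both in minutes and as HH:MM. Descriptive only.
#'
#' @param d a [forage_dataset()].
#' @param by grouping columns of the visit table (default `"species"`).
#' @return data.frame with columns `group`, `n`, `mean_min`, `se_min`,
#'   `mean_time` (HH:MM). `se_min` is `NA` for single-visit groups.
#' @export
mean_activity_time <- function(d, by = "species") {
  stopifnot(inherits(d, "forage_dataset"))
  v <- d$visits
  if (nrow(v) == 0L) {
    warning("no visits: no activity means to report")
    return(data.frame(group = character(0), n = integer(0),
                      mean_min = numeric(0), se_min = numeric(0),
                      mean_time = character(0)))
  }
  key <- interaction(v[by], drop = TRUE, sep = ":")
  out <- do.call(rbind, lapply(levels(key), function(gname) {
    t_g <- v$time_min[key == gname]
    data.frame(
      group = gname, n = length(t_g), mean_min = mean(t_g),
      se_min = if (length(t_g) > 1L) stats::sd(t_g) / sqrt(length(t_g))
               else NA_real_,
      stringsAsFactors = FALSE)
  }))
  out$mean_time <- fmt_hhmm(out$mean_min)
  out
}
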