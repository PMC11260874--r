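#' Configuration for the agent-based visitation simulator
#'
#' Assembles and validates the parameters of [simulate_dataset()]. Defaults
#' emulate an insectary camera-trap trial: five flower stations recorded
#' 08:00--16:00 for 15 days, four species of marked butterflies with
#' morning-peaked activity, females active earlier than males, bout-structured
#' revisitation of a single station, heterogeneous station preference (site
#' fidelity), and imperfect detection.
#'
#' @param n_stations number of flower stations K (>= 2).
#' @param groups data.frame with columns `species`, `n_female`, `n_male`
#'   giving the released individuals per species and sex.
#' @param n_days number of recording days.
#' @param window recording window, minutes since midnight.
#' @param peak mean bout start time (minutes since midnight) for females;
#'   a single value or a vector named by species.
#' @param sex_shift minutes added to `peak` for males (positive = males
#'   later, i.e. females active earlier).
#' @param sd_activity standard deviation of bout start times (minutes).
#' @param bouts_per_day Poisson mean number of feeding bouts per individual
#'   per day.
#' @param bout_size Poisson mean number of *extra* visits per bout beyond
#'   the first (mean visits per bout = `1 + bout_size`).
#' @param gap_mean mean of the exponential intra-bout inter-visit gap
#'   (minutes). Should stay well below the bout-segmentation gap threshold
#'   (20 min by default downstream) so generated bouts are recoverable.
#' @param gap_cap hard upper bound on intra-bout gaps (minutes; exponential
#'   draws above it are redrawn). Defaults to 20, the bout-definition
#'   threshold: a within-bout gap larger than the threshold would, by
#'   definition, belong between bouts. Set `Inf` to disable.
#' @param preference station-choice model, one of:
#'   `list(mode = "uniform")` -- every bout picks a station uniformly;
#'   `list(mode = "fidelity", alpha = a)` -- each individual draws a
#'   Dirichlet(a, ..., a) preference vector once (small `a` = strong site
#'   fidelity, effectively one-hot as `a -> 0`);
#'   `list(mode = "trapline", route = r, switch_prob = e)` -- the individual
#'   walks a fixed cyclic route of stations one step per bout, jumping to a
#'   uniformly random route position with probability `e`.
#' @param p_det probability that a visit triggers a usable video (i.i.d.
#'   thinning per visit).
#' @param p_miss probability that an individual is never detected at all
#'   (applied once per individual, emulating marked butterflies that never
#'   appear on camera).
#' @param min_bout_separation minimum spacing (minutes) enforced between an
#'   individual's bout start times within a day (0 = unconstrained); used to
#'   generate cleanly separated bouts.
#' @param start_date first recording day.
#' @param trial trial label stored on every record.
#' @param seed integer RNG seed; `NULL` uses the current RNG state.
#'
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_stations = 5L,
                       groups = data.frame(
                         species = c("H. erato", "H. melpomene", "H. sara",
                                     "D. iulia"),
                         n_female = c(8L, 8L, 7L, 6L),
                         n_male = c(8L, 8L, 7L, 6L)),
                       n_days = 15L,
                       window = c(480, 960),
                       peak = 660,
                       sex_shift = 30,
                       sd_activity = 90,
                       bouts_per_day = 2,
                       bout_size = 6,
                       gap_mean = 8,
                       gap_cap = 20,
                       preference = list(mode = "fidelity", alpha = 0.3),
                       p_det = 0.9,
                       p_miss = 0.12,
                       min_bout_separation = 0,
                       start_date = as.Date("2022-11-07"),
                       trial = "trial1",
                       seed = NULL) {
  cfg <- list(n_stations = as.integer(n_stations), groups = groups,
              n_days = as.integer(n_days), window = as.numeric(window),
              peak = peak, sex_shift = sex_shift, sd_activity = sd_activity,
              bouts_per_day = bouts_per_day, bout_size = bout_size,
              gap_mean = gap_mean, gap_cap = gap_cap,
              preference = preference, p_det = p_det,
              p_miss = p_miss, min_bout_separation = min_bout_separation,
              start_date = as.Date(start_date), trial = trial, seed = seed)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_stations < 2L) stop("n_stations must be >= 2")
  stopifnot(is.data.frame(cfg$groups),
            all(c("species", "n_female", "n_male") %in% names(cfg$groups)))
  if (length(cfg$window) != 2L || diff(cfg$window) < 1) {
    stop("recording window must span at least 1 minute")
  }
  for (p in c("p_det", "p_miss")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must lie in [0, 1]")
  }
  for (r in c("sd_activity", "bouts_per_day", "gap_mean")) {
    if (cfg[[r]] <= 0) stop(r, " must be positive")
  }
  if (cfg$bout_size < 0) stop("bout_size must be nonnegative")
  if (cfg$gap_cap <= 0) stop("gap_cap must be positive")
  if (cfg$gap_mean >= 20) {
    warning("gap_mean >= 20 min: generated bouts will not be recoverable ",
            "at the default 20-min segmentation threshold")
  }
  mode <- cfg$preference$mode
  if (!mode %in% c("uniform", "fidelity", "trapline")) {
    stop("unknown preference mode: ", mode)
  }
  if (mode == "fidelity" && (is.null(cfg$preference$alpha) ||
                             cfg$preference$alpha <= 0)) {
    stop("fidelity mode needs a positive concentration alpha")
  }
  if (mode == "trapline") {
    route <- cfg$preference$route
    eps <- cfg$preference$switch_prob
    if (is.null(route) || length(route) < 2L) {
      stop("trapline mode needs a route of at least 2 stations")
    }
    if (!all(route %in% seq_len(cfg$n_stations))) {
      stop("trapline route references unknown station(s): ",
           paste(setdiff(route, seq_len(cfg$n_stations)), collapse = ", "))
    }
    if (is.null(eps) || eps < 0 || eps > 1) {
      stop("trapline switch_prob must lie in [0, 1]")
    }
  }
  invisible(cfg)
}

#' Read a simulator configuration from a YAML file
#'
#' The file holds a key tree with the argument names of [sim_config()];
#' `groups` is a list of `{species, n_female, n_male}` entries.
#'
#' @param path YAML file path.
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$groups)) {
    raw$groups <- do.call(rbind, lapply(raw$groups, as.data.frame))
  }
  if (!is.null(raw$start_date)) raw$start_date <- as.Date(raw$start_date)
  do.call(sim_config, raw)
}

#' Simulate a visitation dataset with ground truth
#'
#' Agent-based generator: each marked individual gets a station-preference
#' rule and, per day, a Poisson number of feeding bouts. A bout starts at a
#' truncated-normal time inside the recording window, stays on one station,
#' and contains `1 + Poisson(bout_size)` visits separated by exponential
#' gaps (visits past the window end are discarded). Each visit is detected
#' with probability `p_det`; a fraction `p_miss` of individuals is never
#' detected. The emitted dataset holds detected visits only, canonically
#' sorted; the ground truth records every generated visit with its true bout
#' membership, plus each individual's preference vector and strategy label.
#'
#' Identical configuration and seed reproduce the dataset exactly.
#'
#' @param cfg a [sim_config()].
#' @return list of class `forage_sim` with elements `dataset`
#'   (a [forage_dataset()]) and `truth` (list: `visits` data.frame with
#'   columns `individual, species, sex, date, time_min, station, bout_id,
#'   detected`; `preferences` matrix individuals x stations; `strategy`
#'   named character vector).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  validate_sim_config(cfg)
  if (!is.null(cfg$seed)) set.seed(as.integer(cfg$seed))
  K <- cfg$n_stations
  w <- cfg$window

  # per-individual roster
  g <- cfg$groups
  inds <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
    sp <- g$species[i]
    tag <- gsub("[^A-Za-z]", "", sp)
    rbind(
      if (g$n_female[i] > 0)
        data.frame(species = sp, sex = "female",
                   individual = sprintf("%s-F%02d", tag,
                                        seq_len(g$n_female[i]))),
      if (g$n_male[i] > 0)
        data.frame(species = sp, sex = "male",
                   individual = sprintf("%s-M%02d", tag,
                                        seq_len(g$n_male[i])))
    )
  }))
  n_ind <- nrow(inds)

  peak_of <- function(sp) {
    if (!is.null(names(cfg$peak)) && sp %in% names(cfg$peak)) {
      cfg$peak[[sp]]
    } else {
      cfg$peak[[1]]
    }
  }

  prefs <- matrix(NA_real_, n_ind, K,
                  dimnames = list(inds$individual, NULL))
  strategy <- stats::setNames(rep(cfg$preference$mode, n_ind),
                              inds$individual)
  route_pos <- integer(n_ind)
  for (i in seq_len(n_ind)) {
    prefs[i, ] <- switch(
      cfg$preference$mode,
      uniform = rep(1 / K, K),
      fidelity = rdirichlet1(K, cfg$preference$alpha),
      trapline = {
        route_pos[i] <- sample.int(length(cfg$preference$route), 1L)
        tabulate(cfg$preference$route, K) / length(cfg$preference$route)
      })
  }
  missed <- stats::runif(n_ind) < cfg$p_miss

  bout_id <- 0L
  recs <- vector("list", n_ind)
  for (i in seq_len(n_ind)) {
    mu <- peak_of(inds$species[i]) +
      if (inds$sex[i] == "male") cfg$sex_shift else 0
    day_recs <- vector("list", cfg$n_days)
    for (day in seq_len(cfg$n_days)) {
      nb <- stats::rpois(1L, cfg$bouts_per_day)
      if (nb == 0L) next
      starts <- draw_bout_starts(nb, mu, cfg$sd_activity, w,
                                 cfg$min_bout_separation)
      bouts <- vector("list", nb)
      for (b in seq_len(nb)) {
        st <- switch(
          cfg$preference$mode,
          trapline = {
            route <- cfg$preference$route
            if (stats::runif(1) < cfg$preference$switch_prob) {
              route_pos[i] <- sample.int(length(route), 1L)
            } else {
              route_pos[i] <- route_pos[i] %% length(route) + 1L
            }
            route[route_pos[i]]
          },
          sample.int(K, 1L, prob = prefs[i, ])
        )
        nv <- 1L + stats::rpois(1L, cfg$bout_size)
        times <- starts[b] +
          c(0, cumsum(rexp_capped(nv - 1L, cfg$gap_mean, cfg$gap_cap)))
        times <- times[times <= w[2]]       # truncate at window end
        if (length(times) == 0L) next
        bout_id <- bout_id + 1L
        bouts[[b]] <- data.frame(
          individual = inds$individual[i], species = inds$species[i],
          sex = inds$sex[i],
          date = cfg$start_date + (day - 1L),
          time_min = round(times * 60) / 60,  # whole-second precision
          station = st, bout_id = bout_id,
          stringsAsFactors = FALSE)
      }
      day_recs[[day]] <- do.call(rbind, bouts)
    }
    recs[[i]] <- do.call(rbind, day_recs)
  }
  truth_visits <- do.call(rbind, recs)
  if (is.null(truth_visits)) {
    truth_visits <- data.frame(individual = character(0),
                               species = character(0), sex = character(0),
                               date = as.Date(character(0)),
                               time_min = numeric(0), station = integer(0),
                               bout_id = integer(0))
  }
  # drop second-resolution collisions so records are unique
  truth_visits <- truth_visits[!duplicated(truth_visits[
    c("individual", "date", "time_min", "station")]), , drop = FALSE]
  truth_visits <- canonical_sort(truth_visits)
  rownames(truth_visits) <- NULL

  detected <- stats::runif(nrow(truth_visits)) < cfg$p_det
  detected <- detected & !missed[match(truth_visits$individual,
                                       inds$individual)]
  truth_visits$detected <- detected

  emitted <- truth_visits[detected,
                          c("individual", "species", "sex", "station",
                            "date", "time_min"), drop = FALSE]
  emitted$trial <- cfg$trial
  d <- forage_dataset(emitted, stations = seq_len(K), window = w,
                      roster = inds[, c("individual", "species", "sex")])
  structure(
    list(dataset = d,
         truth = list(visits = truth_visits, preferences = prefs,
                      strategy = strategy),
         config = cfg),
    class = "forage_sim"
  )
}

#' @export
print.forage_sim <- function(x, ...) {
  cat("<forage_sim> ", nrow(x$truth$visits), " generated visits, ",
      n_visits(x$dataset), " detected (mode: ",
      x$config$preference$mode, ")\n", sep = "")
  invisible(x)
}

# exponential(mean) draws rejected above the cap
rexp_capped <- function(n, mean, cap) {
  if (n == 0L) return(numeric(0))
  g <- stats::rexp(n, rate = 1 / mean)
  while (any(bad <- g > cap)) {
    g[bad] <- stats::rexp(sum(bad), rate = 1 / mean)
  }
  g
}

# one Dirichlet(alpha, ..., alpha) draw; degenerates gracefully to one-hot
# as alpha -> 0 (all-zero gamma draws get a uniformly random hot station)
rdirichlet1 <- function(K, alpha) {
  gamma_draw <- stats::rgamma(K, shape = alpha)
  if (sum(gamma_draw) <= 0 || !all(is.finite(gamma_draw))) {
    out <- rep(0, K)
    out[sample.int(K, 1L)] <- 1
    return(out)
  }
  gamma_draw / sum(gamma_draw)
}

# n bout start times ~ Normal(mu, sd) truncated (by rejection) to the
# window; optional minimum pairwise separation, again by rejection with a
# deterministic even-spread fallback so the generator cannot stall
draw_bout_starts <- function(n, mu, sd, window, min_sep = 0) {
  draw1 <- function() {
    for (tries in 1:200) {
      x <- stats::rnorm(1, mu, sd)
      if (x >= window[1] && x <= window[2]) return(x)
    }
    stats::runif(1, window[1], window[2])
  }
  if (min_sep <= 0 || n == 1L) {
    return(sort(vapply(seq_len(n), function(i) draw1(), numeric(1))))
  }
  for (tries in 1:200) {
    x <- sort(vapply(seq_len(n), function(i) draw1(), numeric(1)))
    if (all(diff(x) >= min_sep)) return(x)
  }
  # fall back to an evenly spread schedule satisfying the separation
  span <- diff(window)
  sep <- min(min_sep, span / max(n - 1L, 1L))
  window[1] + (seq_len(n) - 1L) * sep
}
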