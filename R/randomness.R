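#' Per-individual station visit counts
#'
#' @param d a [forage_dataset()] whose station labels lie in `1..K`.
#' @param K number of stations; defaults to `length(d$stations)`.
#' @return integer matrix, one row per individual, `K` columns; unvisited
#'   stations are zero-filled.
#' @export
station_counts <- function(d, K = length(d$stations)) {
  stopifnot(inherits(d, "forage_dataset"))
  v <- d$visits
  if (nrow(v) > 0L && !all(v$station %in% seq_len(K))) {
    stop("station labels outside 1..", K, " found: ",
         paste(sort(unique(v$station[!v$station %in% seq_len(K)])),
               collapse = ", "))
  }
  m <- table(factor(v$individual), factor(v$station, levels = seq_len(K)))
  m <- matrix(as.integer(m), nrow = nrow(m), dimnames = dimnames(m))
  m
}

#' Goodness-of-fit test against uniform random foraging
#'
#' Pearson chi-squared test of one individual's station counts against the
#' null of equal use of all K stations (expected `n/K` visits each, i.e.
#' probability 0.2 with five stations, 0.25 with four). The p-value is
#' either asymptotic (chi-squared with `K - 1` df) or Monte-Carlo from `B`
#' multinomial resamples, `p = (1 + #\{stat* >= stat\}) / (B + 1)`.
#' Individuals with fewer than `min_visits_gof` total visits carry too
#' little information and are returned as exclusion records rather than
#' tests.
#'
#' @param counts integer vector of visits per station (length K).
#' @param alpha significance level for the verdict.
#' @param min_visits_gof minimum total visits required (default 3).
#' @param method `"asymptotic"` or `"monte_carlo"`. With small expected
#'   counts (`n/K < 5`) the asymptotic p-value is unreliable and the result
#'   carries `mc_recommended = TRUE`.
#' @param B Monte-Carlo resamples (default 2000).
#' @return object of class `gof_test`: list with `counts`, `n`, `statistic`,
#'   `df`, `p_value`, `method`, `verdict` (`"random"` / `"non_random"`),
#'   `alpha`, `mc_recommended`, `excluded`, `excluded_reason`.
#' @export
gof_test <- function(counts, alpha = 0.05, min_visits_gof = 3L,
                     method = c("asymptotic", "monte_carlo"), B = 2000L) {
  method <- match.arg(method)
  counts <- as.integer(counts)
  stopifnot(all(counts >= 0L), length(counts) >= 2L)
  K <- length(counts)
  n <- sum(counts)
  base <- list(counts = counts, n = n, K = K, df = K - 1L, alpha = alpha,
               method = method)
  if (n < min_visits_gof) {
    out <- c(base, list(statistic = NA_real_, p_value = NA_real_,
                        verdict = NA_character_, mc_recommended = FALSE,
                        excluded = TRUE,
                        excluded_reason = sprintf(
                          "only %d visits (< %d required)", n,
                          min_visits_gof)))
    class(out) <- "gof_test"
    return(out)
  }
  expected <- n / K
  statistic <- sum((counts - expected)^2 / expected)
  p <- if (method == "asymptotic") {
    stats::pchisq(statistic, df = K - 1L, lower.tail = FALSE)
  } else {
    sim <- stats::rmultinom(B, n, rep(1 / K, K))
    stat_star <- colSums((sim - expected)^2 / expected)
    (1 + sum(stat_star >= statistic - 1e-9)) / (B + 1)
  }
  out <- c(base, list(
    statistic = statistic, p_value = p,
    verdict = if (p < alpha) "non_random" else "random",
    mc_recommended = method == "asymptotic" && expected < 5,
    excluded = FALSE, excluded_reason = NA_character_))
  class(out) <- "gof_test"
  out
}

#' @export
print.gof_test <- function(x, ...) {
  if (x$excluded) {
    cat("Uniform-foraging GOF: excluded (", x$excluded_reason, ")\n",
        sep = "")
  } else {
    cat(sprintf(
      "Uniform-foraging GOF: X^2 = %.3f, df = %d, p = %.4g (%s) -> %s\n",
      x$statistic, x$df, x$p_value, x$method, x$verdict))
    if (isTRUE(x$mc_recommended)) {
      cat("  note: expected count < 5; Monte-Carlo p recommended\n")
    }
  }
  invisible(x)
}

#' Randomness tests for every individual in a dataset
#'
#' Applies [gof_test()] to each individual's station counts. Individuals
#' below the visit threshold are listed in the `excluded` attribute rather
#' than tested.
#'
#' @param d a [forage_dataset()].
#' @param K number of stations (default from `d`).
#' @inheritParams gof_test
#' @return data.frame with one row per tested individual (`individual`,
#'   `species`, `sex`, `n`, `statistic`, `df`, `p_value`, `method`,
#'   `verdict`) and attribute `excluded` (data.frame `individual`, `n`,
#'   `reason`).
#' @export
randomness_tests <- function(d, K = length(d$stations), alpha = 0.05,
                             min_visits_gof = 3L,
                             method = c("asymptotic", "monte_carlo"),
                             B = 2000L) {
  method <- match.arg(method)
  cm <- station_counts(d, K)
  v <- d$visits
  meta <- unique(v[, c("individual", "species", "sex")])
  rows <- list(); excl <- list()
  for (id in rownames(cm)) {
    tst <- gof_test(cm[id, ], alpha = alpha,
                    min_visits_gof = min_visits_gof, method = method, B = B)
    m <- meta[meta$individual == id, , drop = FALSE][1L, ]
    if (tst$excluded) {
      excl[[id]] <- data.frame(individual = id, n = tst$n,
                               reason = tst$excluded_reason,
                               stringsAsFactors = FALSE)
    } else {
      rows[[id]] <- data.frame(
        individual = id, species = m$species, sex = m$sex, n = tst$n,
        statistic = tst$statistic, df = tst$df, p_value = tst$p_value,
        method = method, verdict = tst$verdict, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(individual = character(0), species = character(0),
               sex = character(0), n = integer(0), statistic = numeric(0),
               df = integer(0), p_value = numeric(0), method = character(0),
               verdict = character(0))
  rownames(out) <- NULL
  attr(out, "excluded") <- if (length(excl)) {
    e <- do.call(rbind, excl); rownames(e) <- NULL; e
  } else data.frame(individual = character(0), n = integer(0),
                    reason = character(0))
  attr(out, "alpha") <- alpha
  out
}

#' Proportion of individuals consistent with random foraging
#'
#' @param tests result of [randomness_tests()].
#' @param by grouping columns of the test table (default `"species"`).
#' @return data.frame with columns `group`, `n_tested`, `n_random`,
#'   `prop_random`, `percent_random`.
#' @export
randomness_summary <- function(tests, by = "species") {
  if (nrow(tests) == 0L) stop("no randomness tests to summarise")
  key <- interaction(tests[by], drop = TRUE, sep = ":")
  out <- do.call(rbind, lapply(levels(key), function(gname) {
    tt <- tests[key == gname, , drop = FALSE]
    nr <- sum(tt$verdict == "random")
    data.frame(group = gname, n_tested = nrow(tt), n_random = nr,
               prop_random = nr / nrow(tt),
               percent_random = round(100 * nr / nrow(tt), 1),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Proportion of available stations each individual used
#'
#' @param d a [forage_dataset()].
#' @param K number of stations (default from `d`).
#' @return data.frame with columns `individual`, `species`,
#'   `distinct_stations`, `proportion` (= distinct / K).
#' @export
station_usage <- function(d, K = length(d$stations)) {
  stopifnot(inherits(d, "forage_dataset"))
  cm <- station_counts(d, K)
  v <- d$visits
  meta <- unique(v[, c("individual", "species")])
  out <- data.frame(
    individual = rownames(cm),
    species = meta$species[match(rownames(cm), meta$individual)],
    distinct_stations = as.integer(rowSums(cm > 0)),
    stringsAsFactors = FALSE)
  out$proportion <- out$distinct_stations / K
  rownames(out) <- NULL
  out
}
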