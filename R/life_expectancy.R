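#' Build an abridged (Chiang-style) life table
#'
#' Converts an age-specific mortality schedule into the standard abridged
#' life-table columns. For each band of width n with central death rate m and
#' average years lived in the band by those dying in it a (the a_x
#' convention, default n/2):
#' \deqn{q_x = n m_x / (1 + (n - a_x) m_x)}
#' with survivors l (radix 100,000 at the first band), deaths d = l q,
#' person-years L = n (l - d) + a d, cumulative person-years T and remaining
#' life expectancy e = T / l. The open terminal band has q = 1 and
#' L = l / m (exponential open-interval convention).
#'
#' @param rates numeric vector of central mortality rates (deaths per
#'   person-year), one per band; all > 0. Alternatively a schedule data frame
#'   with columns \code{x}, \code{n}, \code{rate} (then \code{bands} is taken
#'   from it).
#' @param bands band table from \code{\link{age_bands}}.
#' @param radix survivors at the first exact age (default 100,000).
#' @param ax optional numeric vector of a_x values (finite bands); default
#'   n/2.
#' @return data frame with columns \code{x, n, mx, ax, qx, lx, dx, Lx, Tx, ex}.
#' @export
build_life_table <- function(rates, bands = age_bands(), radix = 1e5,
                             ax = NULL) {
  if (is.data.frame(rates)) {
    if (!all(c("x", "n", "rate") %in% names(rates)))
      stop("schedule data frame needs columns x, n, rate")
    bands <- rates[c("x", "n")]
    rates <- rates$rate
  }
  .check_bands(bands)
  k <- nrow(bands)
  if (length(rates) != k)
    stop("band mismatch: ", length(rates), " rates for ", k, " bands")
  if (any(!is.finite(rates)) || any(rates <= 0))
    stop("all mortality rates must be positive and finite")
  n <- bands$n
  if (is.null(ax)) ax <- n / 2
  ax[k] <- NA  # terminal band has no a_x under the open-interval convention
  if (k > 1L && any(ax[-k] <= 0 | ax[-k] >= n[-k]))
    stop("a_x must lie strictly inside each finite band")

  qx <- numeric(k)
  if (k > 1L) {
    i <- seq_len(k - 1L)
    qx[i] <- n[i] * rates[i] / (1 + (n[i] - ax[i]) * rates[i])
    qx[i] <- pmin(qx[i], 1)
  }
  qx[k] <- 1

  lx <- numeric(k)
  lx[1] <- radix
  if (k > 1L) for (i in seq_len(k - 1L)) lx[i + 1L] <- lx[i] * (1 - qx[i])
  dx <- lx * qx
  Lx <- numeric(k)
  if (k > 1L) {
    i <- seq_len(k - 1L)
    Lx[i] <- n[i] * (lx[i] - dx[i]) + ax[i] * dx[i]
  }
  Lx[k] <- lx[k] / rates[k]
  Tx <- rev(cumsum(rev(Lx)))
  # under very high rates q can cap at 1 before the terminal band; the
  # extinct tail carries zero survivors and zero remaining expectancy
  ex <- ifelse(lx > 0, Tx / lx, 0)
  data.frame(x = bands$x, n = n, mx = rates, ax = ax, qx = qx,
             lx = lx, dx = dx, Lx = Lx, Tx = Tx, ex = ex)
}

#' Life expectancy at the first table age under a group hazard ratio
#'
#' Scales every band of a reference mortality schedule by a group hazard
#' ratio (proportional scaling across ages), rebuilds the life table and
#' returns the remaining life expectancy at the first band's exact age
#' (age 50 under the default band structure). A hazard ratio of 1 reproduces
#' the reference life expectancy exactly.
#'
#' @param schedule reference schedule (data frame with \code{x}, \code{n},
#'   \code{rate}) or a numeric rate vector.
#' @param hr group hazard ratio (> 0).
#' @param bands band table (ignored when \code{schedule} is a data frame).
#' @return life expectancy in years.
#' @export
life_expectancy_at_50 <- function(schedule, hr = 1, bands = age_bands()) {
  if (!is.numeric(hr) || length(hr) != 1L || hr <= 0)
    stop("hr must be a positive scalar")
  if (is.data.frame(schedule)) {
    schedule$rate <- schedule$rate * hr
    lt <- build_life_table(schedule)
  } else {
    lt <- build_life_table(schedule * hr, bands)
  }
  lt$ex[1]
}

#' Years of life lost between two life expectancies
#'
#' Signed difference \code{e50_a - e50_b}; positive when group a outlives
#' group b.
#'
#' @param e50_a,e50_b life expectancies at the same exact age, from tables
#'   over identical bands.
#' @return difference in years.
#' @export
years_of_life_lost <- function(e50_a, e50_b) {
  if (!is.numeric(e50_a) || !is.numeric(e50_b))
    stop("life expectancies must be numeric")
  e50_a - e50_b
}

#' Monte-Carlo (parametric bootstrap) CI for life expectancy
#'
#' Propagates the sampling uncertainty of a log hazard ratio into life
#' expectancy: each run draws beta* ~ Normal(beta, se^2), rebuilds the life
#' table with HR = exp(beta*) applied to the reference schedule, and collects
#' the resulting life expectancy. Bounds are the empirical 2.5th and 97.5th
#' percentiles over the runs (percentile bootstrap); the point estimate uses
#' beta itself.
#'
#' @param beta log hazard ratio.
#' @param se its standard error (>= 0).
#' @param schedule reference mortality schedule (data frame with \code{x},
#'   \code{n}, \code{rate}).
#' @param runs number of bootstrap draws (default 1000, >= 2).
#' @param seed integer seed; results are deterministic given it.
#' @param level confidence level (default 0.95).
#' @return list with \code{e50} (point), \code{lower}, \code{upper}, and the
#'   vector of \code{draws}.
#' @export
monte_carlo_ci <- function(beta, se, schedule, runs = 1000, seed = 1L,
                           level = 0.95) {
  if (se < 0) stop("se must be >= 0")
  if (runs < 2) stop("runs must be >= 2")
  point <- life_expectancy_at_50(schedule, exp(beta))
  set.seed(seed)
  bs <- stats::rnorm(runs, beta, se)
  draws <- vapply(bs, function(b) life_expectancy_at_50(schedule, exp(b)),
                  numeric(1))
  alpha <- (1 - level) / 2
  qs <- stats::quantile(draws, c(alpha, 1 - alpha), names = FALSE, type = 7)
  list(e50 = point, lower = qs[1], upper = qs[2], draws = draws)
}

#' Empirical age-band mortality rates from a cohort
#'
#' Splits each participant's follow-up over attained-age bands and tallies
#' person-years and deaths (optionally by cause) per band, returning central
#' death rates m_x = deaths / person-years. Bands that accrue person-years
#' but no deaths can optionally inherit the nearest preceding positive rate
#' so the schedule stays usable by \code{\link{build_life_table}}.
#'
#' @param cohort data frame with \code{age}, \code{followup_years},
#'   \code{died} and (for cause-specific rates) \code{cause}.
#' @param bands band table from \code{\link{age_bands}}.
#' @param by_cause logical; also return CVD / non-CVD specific rates.
#' @param fill_empty logical; carry the last positive all-cause rate into
#'   zero-death bands (default TRUE).
#' @return data frame with \code{x}, \code{n}, \code{person_years},
#'   \code{deaths}, \code{rate} and, when \code{by_cause}, \code{deaths_cvd},
#'   \code{deaths_noncvd}, \code{rate_cvd}, \code{rate_noncvd}.
#' @export
cohort_mortality_rates <- function(cohort, bands = age_bands(),
                                   by_cause = FALSE, fill_empty = TRUE) {
  .check_bands(bands)
  k <- nrow(bands)
  a0 <- cohort$age
  a1 <- cohort$age + cohort$followup_years
  upper <- bands$x + bands$n
  py <- deaths <- d_cvd <- numeric(k)
  for (i in seq_len(k)) {
    lo <- bands$x[i]; hi <- upper[i]
    py[i] <- sum(pmax(0, pmin(a1, hi) - pmax(a0, lo)))
    in_band <- cohort$died & a1 >= lo & a1 < hi
    deaths[i] <- sum(in_band)
    if (by_cause) d_cvd[i] <- sum(in_band & cohort$cause == "CVD")
  }
  rate <- ifelse(py > 0, deaths / py, NA_real_)
  rate_cvd <- ifelse(py > 0, d_cvd / py, NA_real_)
  rate_noncvd <- ifelse(py > 0, (deaths - d_cvd) / py, NA_real_)
  if (fill_empty) {
    # borrow the nearest informative band (cause rates come along so that
    # rate == rate_cvd + rate_noncvd stays exact)
    for (i in which(is.na(rate) | rate == 0)) {
      prev <- which(!is.na(rate) & rate > 0 & seq_len(k) < i)
      src <- if (length(prev)) max(prev) else {
        nxt <- which(!is.na(rate) & rate > 0 & seq_len(k) > i)
        if (length(nxt)) min(nxt) else NA_integer_
      }
      if (!is.na(src)) {
        rate[i] <- rate[src]
        rate_cvd[i] <- rate_cvd[src]
        rate_noncvd[i] <- rate_noncvd[src]
      }
    }
  }
  out <- data.frame(x = bands$x, n = bands$n, person_years = py,
                    deaths = deaths, rate = rate)
  if (by_cause) {
    out$deaths_cvd <- d_cvd
    out$deaths_noncvd <- deaths - d_cvd
    out$rate_cvd <- rate_cvd
    out$rate_noncvd <- rate_noncvd
  }
  out
}
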