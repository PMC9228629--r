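#' Simulate individual urinary biomarker concentrations
#'
#' Draws individual-level urinary metabolite concentrations from a lognormal
#' distribution parameterised by its median and the standard deviation of
#' the log concentration - the standard generative family for urinary
#' biomarkers, and the multiplicative framing in which population
#' variability is usually quoted as a P95/P50 ratio
#' (`ratio = exp(1.645 * sigma_log)`; observed ratios of about 4 and about
#' 10 correspond to `sigma_log` of about 0.84 and 1.40). Values below an
#' optional detection limit are flagged censored, emulating studies that
#' cannot report percentiles because too many samples fall below the limit.
#'
#' @param median Population median concentration in ug/L (positive).
#' @param sigma_log Standard deviation of the natural-log concentration
#'   (>= 0; 0 gives a degenerate population at the median).
#' @param n Number of individuals (>= 1).
#' @param seed Integer seed (mandatory).
#' @param lod Optional detection limit in ug/L.
#'
#' @return A tibble with columns `value` (ug/L) and `censored` (logical).
#' @export
#'
#' @examples
#' simulate_population(1.5, 0.84, n = 100, seed = 1)
simulate_population <- function(median, sigma_log, n, seed, lod = NULL) {
  if (median <= 0) abort("`median` must be positive.")
  if (sigma_log < 0) abort("`sigma_log` must be non-negative.")
  if (n < 1) abort("`n` must be at least 1.")
  if (missing(seed) || is.null(seed)) abort("A seed is required.")
  values <- withr::with_seed(seed, rlnorm(n, meanlog = log(median),
                                          sdlog = sigma_log))
  tibble::tibble(
    value = values,
    censored = if (is.null(lod)) FALSE else values < lod
  )
}

#' Two-sided percentile-bootstrap confidence interval for the 95th percentile
#'
#' Resamples the values with replacement `n_boot` times, recomputes the
#' 95th percentile of each resample (linear-interpolation quantiles) and
#' returns the percentile-method confidence interval.
#'
#' @param values Numeric vector (length >= 20).
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#'
#' @return Named numeric vector `c(lower = , upper = )`.
#' @export
bootstrap_ci_p95 <- function(values, n_boot = 1000, seed, conf = 0.95) {
  if (length(values) < 20L) {
    abort("At least 20 values are required for a bootstrap CI.")
  }
  if (missing(seed) || is.null(seed)) abort("A seed is required.")
  boot <- withr::with_seed(seed, {
    idx <- matrix(sample.int(length(values), length(values) * n_boot,
                             replace = TRUE),
                  nrow = length(values))
    apply(idx, 2, function(i) quantile(values[i], 0.95, type = 7,
                                       names = FALSE))
  })
  alpha <- (1 - conf) / 2
  q <- quantile(boot, c(alpha, 1 - alpha), type = 7, names = FALSE)
  c(lower = q[1], upper = q[2])
}

#' Aggregate simulated individuals to a biomonitoring percentile record
#'
#' Produces the aggregated record shape consumed by the ingestion stage:
#' median and 95th percentile by linear-interpolation quantiles, and the
#' upper bound of the two-sided 95% percentile-bootstrap confidence interval
#' of the 95th percentile. When the censored fraction exceeds `nr_cutoff`
#' the record reports missing percentiles (the not-reported convention used
#' when most samples fall below the detection limit).
#'
#' @param sim Tibble from [simulate_population()] (columns `value`,
#'   `censored`), or a bare numeric vector.
#' @param study_id,country,population,years Record metadata.
#' @param n_boot Bootstrap resamples for the CI.
#' @param seed Integer seed for the bootstrap.
#' @param nr_cutoff Censored fraction above which percentiles are withheld.
#'
#' @return A one-row tibble in the [read_hbm_records()] schema.
#' @export
aggregate_to_record <- function(sim, study_id, country = NA_character_,
                                population = "adults", years = NA_character_,
                                n_boot = 1000, seed, nr_cutoff = 0.6) {
  if (is.numeric(sim)) sim <- tibble::tibble(value = sim, censored = FALSE)
  values <- sim$value
  if (length(values) < 20L) {
    abort("At least 20 values are required to aggregate a record.")
  }
  if (missing(seed) || is.null(seed)) abort("A seed is required.")
  censored_frac <- mean(sim$censored)
  if (censored_frac > nr_cutoff) {
    p50 <- p95 <- uci <- mx <- NA_real_
  } else {
    p50 <- quantile(values, 0.50, type = 7, names = FALSE)
    p95 <- quantile(values, 0.95, type = 7, names = FALSE)
    uci <- unname(bootstrap_ci_p95(values, n_boot = n_boot, seed = seed)["upper"])
    uci <- max(uci, p95)  # upper bound can not undercut the point estimate
    mx <- max(values)
  }
  tibble::tibble(
    study_id = study_id, country = country, population = population,
    years = years, n = length(values),
    p50 = p50, p95 = p95, upper_ci_p95 = uci, max = mx,
    adjusted = FALSE, censored_fraction = censored_frac
  )
}

#' Simulate a dietary-risk table in the %-of-ADI reporting shape
#'
#' Emulates the per-diet dietary risk tables of the annual monitoring
#' reports: for each year and diet, the highest calculated exposure of each
#' pesticide is drawn uniformly within an era-specific %-of-ADI range. Two
#' eras reflect the regulatory regime shift: report years before
#' `era_break` use `range_pre`, later years `range_post`. Zero-width ranges
#' give deterministic tables.
#'
#' @param years Report years.
#' @param n_diets Diets per year.
#' @param range_pre,range_post Length-2 numeric: min/max %ADI per era.
#' @param era_break First year of the post era.
#' @param pesticides Character vector of pesticide identities.
#' @param population Population label for every diet.
#' @param seed Integer seed.
#'
#' @return A tibble with columns `diet_label`, `year`, `population`,
#'   `pesticide`, `percent_adi` (`n_diets * length(years) *
#'   length(pesticides)` rows).
#' @export
simulate_diet_table <- function(years = 2012:2019, n_diets = 30,
                                range_pre = c(5, 100),
                                range_post = c(5, 100),
                                era_break = 2016,
                                pesticides = c("chlorpyrifos",
                                               "chlorpyrifos-methyl"),
                                population = "general",
                                seed) {
  if (missing(seed) || is.null(seed)) abort("A seed is required.")
  stopifnot(length(range_pre) == 2L, length(range_post) == 2L,
            range_pre[1] <= range_pre[2], range_post[1] <= range_post[2],
            all(range_pre >= 0), all(range_post >= 0), n_diets >= 1)
  grid <- tidyr::crossing(
    year = years,
    diet_label = sprintf("diet_%02d", seq_len(n_diets)),
    pesticide = pesticides
  )
  lo <- ifelse(grid$year >= era_break, range_post[1], range_pre[1])
  hi <- ifelse(grid$year >= era_break, range_post[2], range_pre[2])
  grid$percent_adi <- withr::with_seed(seed, runif(nrow(grid), lo, hi))
  grid$population <- population
  grid[, c("diet_label", "year", "population", "pesticide", "percent_adi")]
}
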