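## Synthetic GBD-like panels with a known latent care-quality scalar --------

default_age_incidence <- function(age_bins) {
  mid <- age_bin_midpoints(age_bins)
  base <- 0.2 + 0.055 * mid
  # incidence ascends sharply once past age 75
  rate <- ifelse(mid >= 75, base * (1 + 0.12 * (mid - 75)), base)
  stats::setNames(rate, age_bins)
}

default_life_expectancy <- function(age_bins) {
  mid <- age_bin_midpoints(age_bins)
  stats::setNames(pmax(87.5 - mid, 2), age_bins)
}

age_bin_midpoints <- function(age_bins) {
  vapply(age_bins, function(b) {
    if (b == "95 plus") return(97.5)
    lo <- as.numeric(sub(" to .*", "", b))
    lo + 2.5
  }, numeric(1))
}

#' Configuration for the synthetic burden-panel generator
#'
#' Defaults encode the qualitative epidemiology the generator emulates:
#' female incidence 2.5x male, an age-incidence profile that rises with age
#' and ascends sharply past 75, case fatality and prevalence duration driven
#' by a latent per-location care-quality scalar, and a reference/current
#' year pair whose populations differ by growth and an aging tilt.
#'
#' @param n_locations Number of locations.
#' @param years Integer vector; the first is the reference year, the last
#'   the current year.
#' @param age_bins Ordered age-bin labels (5-year GBD bins by default).
#' @param female_incidence_multiplier Female/male incidence-rate ratio.
#' @param baseline_age_incidence Named vector, age bin -> male incidence
#'   rate per 100,000.
#' @param case_fatality_bounds `c(m_min, m_max)`: a location of quality q
#'   has mortality-to-incidence ratio `m_max - (m_max - m_min) * q`.
#' @param mean_duration_bounds `c(d_min, d_max)` years: prevalence equals
#'   incidence times `d_min + (d_max - d_min) * q`.
#' @param disability_weight YLD per prevalent case-year, in (0, 1).
#' @param reference_life_expectancy Named vector, age bin -> residual life
#'   expectancy (years) used for YLLs.
#' @param noise_sd Log-scale SD of the multiplicative noise applied per
#'   stratum to incidence, deaths, and prevalence (0 = noiseless).
#' @param pop_growth_factor Current-year total population relative to the
#'   reference year.
#' @param aging_shift Non-negative tilt moving current-year population mass
#'   into older bins (0 = unchanged age structure).
#' @param base_population Reference-year population per location (both
#'   sexes).
#' @param seed Integer seed; the generator is deterministic given the
#'   config.
#' @return A `synthetic_config` list, validated.
#' @export
synthetic_config <- function(n_locations = 20,
                             years = c(1990L, 2017L),
                             age_bins = gbd_age_bins(),
                             female_incidence_multiplier = 2.5,
                             baseline_age_incidence = default_age_incidence(age_bins),
                             case_fatality_bounds = c(0.02, 0.6),
                             mean_duration_bounds = c(2, 12),
                             disability_weight = 0.1,
                             reference_life_expectancy = default_life_expectancy(age_bins),
                             noise_sd = 0.1,
                             pop_growth_factor = 1.5,
                             aging_shift = 0.5,
                             base_population = 5e6,
                             seed = 1L) {
  cfg <- list(
    n_locations = as.integer(n_locations), years = as.integer(years),
    age_bins = age_bins, female_incidence_multiplier = female_incidence_multiplier,
    baseline_age_incidence = baseline_age_incidence,
    case_fatality_bounds = case_fatality_bounds,
    mean_duration_bounds = mean_duration_bounds,
    disability_weight = disability_weight,
    reference_life_expectancy = reference_life_expectancy,
    noise_sd = noise_sd, pop_growth_factor = pop_growth_factor,
    aging_shift = aging_shift, base_population = base_population,
    seed = as.integer(seed)
  )
  validate_synthetic_config(cfg)
  class(cfg) <- "synthetic_config"
  cfg
}

validate_synthetic_config <- function(cfg) {
  if (length(cfg$years) < 2) {
    stop("config error: at least a reference and a current year are required",
         call. = FALSE)
  }
  if (length(cfg$age_bins) == 0) {
    stop("config error: age_bins must be non-empty", call. = FALSE)
  }
  if (cfg$n_locations < 1) stop("config error: n_locations < 1", call. = FALSE)
  m <- cfg$case_fatality_bounds
  d <- cfg$mean_duration_bounds
  if (m[1] > m[2] || m[1] <= 0 || m[2] >= 1) {
    stop("config error: case_fatality_bounds must satisfy 0 < m_min <= m_max < 1",
         call. = FALSE)
  }
  if (d[1] > d[2] || d[1] <= 0) {
    stop("config error: mean_duration_bounds must satisfy 0 < d_min <= d_max",
         call. = FALSE)
  }
  if (cfg$disability_weight <= 0 || cfg$disability_weight >= 1) {
    stop("config error: disability_weight must lie in (0, 1)", call. = FALSE)
  }
  if (cfg$noise_sd < 0) stop("config error: noise_sd < 0", call. = FALSE)
  if (any(cfg$baseline_age_incidence < 0)) {
    stop("config error: negative baseline incidence rate", call. = FALSE)
  }
  if (!all(cfg$age_bins %in% names(cfg$baseline_age_incidence)) ||
      !all(cfg$age_bins %in% names(cfg$reference_life_expectancy))) {
    stop("config error: age maps must cover every age bin", call. = FALSE)
  }
  if (cfg$pop_growth_factor <= 0) {
    stop("config error: pop_growth_factor must be positive", call. = FALSE)
  }
  invisible(cfg)
}

# Discretized beta-shaped age pyramid; `shift` moves mass into older bins.
age_pyramid <- function(n_bins, shift = 0) {
  x <- (seq_len(n_bins) - 0.5) / n_bins
  dens <- stats::dbeta(x, 2 + shift, max(4 - shift, 0.5))
  dens / sum(dens)
}

#' Generate a synthetic burden panel, population table, and latent truth
#'
#' For each location a latent quality scalar q in (0, 1) drives the
#' mortality-to-incidence ratio downward, the prevalence-to-incidence ratio
#' upward, and (through deaths and prevalence) the YLL-to-YLD ratio
#' downward. YLDs are prevalence times the disability weight, YLLs are
#' deaths times residual life expectancy, and DALYs = YLLs + YLDs holds
#' exactly, noise included, because noise is applied to incidence, deaths,
#' and prevalence before the life-year measures are derived.
#'
#' @param config A [synthetic_config()].
#' @return List with `cells` (burden cells in the [read_gbd_csv()] layout,
#'   counts), `population` (location/year/sex/age_group/population), and
#'   `truth` (latent `quality` per location, the config, and the noiseless
#'   per-stratum measures).
#' @export
generate_panel <- function(config) {
  validate_synthetic_config(config)
  set.seed(config$seed)
  locs <- sprintf("loc_%02d", seq_len(config$n_locations))
  quality <- stats::setNames(stats::runif(config$n_locations, 0.05, 0.95), locs)
  ref_year <- config$years[1]
  cur_year <- config$years[length(config$years)]
  years <- unique(c(ref_year, cur_year))
  nb <- length(config$age_bins)

  grid <- expand.grid(
    location = locs, year = years, sex = c("female", "male"),
    age_group = config$age_bins,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid <- dplyr::arrange(
    grid, .data$location, .data$year, .data$sex,
    match(.data$age_group, config$age_bins)
  )

  dens_ref <- age_pyramid(nb, 0)
  dens_cur <- age_pyramid(nb, config$aging_shift)
  bin_i <- match(grid$age_group, config$age_bins)
  dens <- ifelse(grid$year == ref_year, dens_ref[bin_i], dens_cur[bin_i])
  total <- ifelse(grid$year == ref_year, config$base_population,
                  config$base_population * config$pop_growth_factor)
  grid$population <- total * dens / 2  # equal sex split

  q <- quality[grid$location]
  m <- config$case_fatality_bounds
  d <- config$mean_duration_bounds
  mir_true <- m[2] - (m[2] - m[1]) * q
  dur_true <- d[1] + (d[2] - d[1]) * q
  sex_mult <- ifelse(grid$sex == "female", config$female_incidence_multiplier, 1)
  rate <- config$baseline_age_incidence[grid$age_group] * sex_mult
  le <- config$reference_life_expectancy[grid$age_group]

  inc0 <- grid$population * rate / 1e5
  deaths0 <- inc0 * mir_true
  prev0 <- inc0 * dur_true
  ylds0 <- prev0 * config$disability_weight
  ylls0 <- deaths0 * le
  dalys0 <- ylls0 + ylds0

  n <- nrow(grid)
  noise <- function() {
    if (config$noise_sd == 0) rep(1, n)
    else exp(stats::rnorm(n, 0, config$noise_sd))
  }
  incidence  <- inc0 * noise()
  deaths     <- deaths0 * noise()
  prevalence <- prev0 * noise()
  ylds  <- prevalence * config$disability_weight
  ylls  <- deaths * le
  dalys <- ylls + ylds

  panel <- tibble::tibble(
    location = grid$location, year = as.integer(grid$year), sex = grid$sex,
    age_group = grid$age_group,
    incidence = incidence, prevalence = prevalence, deaths = deaths,
    dalys = dalys, ylls = ylls, ylds = ylds
  )
  noiseless <- tibble::tibble(
    location = grid$location, year = as.integer(grid$year), sex = grid$sex,
    age_group = grid$age_group,
    incidence = inc0, prevalence = prev0, deaths = deaths0,
    dalys = dalys0, ylls = ylls0, ylds = ylds0
  )
  cells <- tidyr::pivot_longer(panel, dplyr::all_of(gbd_measures()),
                               names_to = "measure", values_to = "value")
  cells$metric <- "count"
  cells$lower <- NA_real_
  cells$upper <- NA_real_
  cells <- cells[, c("location", "year", "sex", "age_group",
                     "measure", "metric", "value", "lower", "upper")]
  population <- tibble::tibble(
    location = grid$location, year = as.integer(grid$year), sex = grid$sex,
    age_group = grid$age_group, population = grid$population
  )
  list(
    cells = cells, population = population,
    truth = list(quality = quality, config = config, noiseless = noiseless)
  )
}

#' Build a decomposition test case with its analytic answer
#'
#' Constructs reference/current populations and age-specific rates together
#' with the counterfactual expected counts and contribution percentages
#' computed directly from their definitions, for use as the expected answer
#' in recovery tests of the decomposition pipeline.
#'
#' @param rates_ref Named vector, age -> reference incidence rate per
#'   100,000.
#' @param pop_ref Named vector, age -> reference population count.
#' @param pop_cur Named vector, age -> current population count.
#' @param rates_cur Named vector of current rates (defaults to `rates_ref`).
#' @return List with the inputs, `structure_ref`, the counts `n_ref`,
#'   `n_cur`, `e_growth`, `e_growth_aging`, and the percentages
#'   `pct_growth`, `pct_aging`, `pct_rates`, `pct_overall`.
#' @export
generate_decomposition_case <- function(rates_ref, pop_ref, pop_cur,
                                        rates_cur = rates_ref) {
  ages <- names(rates_ref)
  if (is.null(ages) ||
      !setequal(ages, names(pop_ref)) || !setequal(ages, names(pop_cur)) ||
      !setequal(ages, names(rates_cur))) {
    stop("alignment error: age names must match across all inputs",
         call. = FALSE)
  }
  pop_ref <- pop_ref[ages]; pop_cur <- pop_cur[ages]; rates_cur <- rates_cur[ages]
  if (any(c(rates_ref, rates_cur) < 0) || any(c(pop_ref, pop_cur) < 0)) {
    stop("domain error: rates and populations must be non-negative",
         call. = FALSE)
  }
  if (sum(pop_ref) == 0 || sum(pop_cur) == 0) {
    stop("config error: degenerate all-zero population", call. = FALSE)
  }
  structure_ref <- pop_ref / sum(pop_ref)
  n_ref <- sum(pop_ref * rates_ref) / 1e5
  n_cur <- sum(pop_cur * rates_cur) / 1e5
  e_growth <- sum(pop_cur) * sum(structure_ref * rates_ref) / 1e5
  e_growth_aging <- sum(pop_cur * rates_ref) / 1e5
  if (n_ref == 0) {
    stop("config error: reference expected count is zero", call. = FALSE)
  }
  list(
    rates_ref = rates_ref, rates_cur = rates_cur,
    pop_ref = pop_ref, pop_cur = pop_cur, structure_ref = structure_ref,
    n_ref = n_ref, n_cur = n_cur,
    e_growth = e_growth, e_growth_aging = e_growth_aging,
    pct_growth = 100 * (e_growth - n_ref) / n_ref,
    pct_aging = 100 * (e_growth_aging - e_growth) / n_ref,
    pct_rates = 100 * (n_cur - e_growth_aging) / n_ref,
    pct_overall = 100 * (n_cur - n_ref) / n_ref
  )
}
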