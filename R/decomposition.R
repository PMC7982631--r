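## Counterfactual decomposition of incidence-count change -------------------

#' Expected current-year counts under two counterfactual scenarios
#'
#' Scenario 1 (`e_growth`) applies the reference-year age-specific rates
#' and the reference-year age structure to the current total population:
#' only population size has changed. Scenario 2 (`e_growth_aging`) applies
#' the reference-year rates to the current population size *and* structure:
#' size and aging have changed, rates have not.
#'
#' @param rates_ref Named vector, age -> reference incidence rate per
#'   100,000.
#' @param structure_ref Named vector, reference age distribution (sums to 1
#'   within 1e-9).
#' @param pop_cur Named vector, age -> current population count.
#' @return Named numeric vector `c(e_growth, e_growth_aging)`.
#' @export
expected_counts <- function(rates_ref, structure_ref, pop_cur) {
  ages <- names(rates_ref)
  if (is.null(ages) || !setequal(ages, names(structure_ref)) ||
      !setequal(ages, names(pop_cur))) {
    stop("alignment error: age keys must be identical across the three maps",
         call. = FALSE)
  }
  structure_ref <- structure_ref[ages]
  pop_cur <- pop_cur[ages]
  if (abs(sum(structure_ref) - 1) > 1e-9) {
    stop(sprintf("domain error: structure_ref sums to %.12f, expected 1",
                 sum(structure_ref)), call. = FALSE)
  }
  c(
    e_growth = sum(pop_cur) * sum(structure_ref * rates_ref) / 1e5,
    e_growth_aging = sum(pop_cur * rates_ref) / 1e5
  )
}

#' Three-factor decomposition of a count change
#'
#' Attributes the change from `n_ref` to `n_cur` to population growth
#' (`e_growth` vs `n_ref`), population aging (`e_growth_aging` vs
#' `e_growth`), and age-specific rates (`n_cur` vs `e_growth_aging`), each
#' expressed as a percent of the reference count. The three contributions
#' telescope, so they sum to the overall percent change identically.
#'
#' @param n_ref Reference-year count (> 0).
#' @param n_cur Current-year count.
#' @param e_growth,e_growth_aging Counterfactual expected counts from
#'   [expected_counts()].
#' @return One-row tibble: the four counts plus `pct_growth`, `pct_aging`,
#'   `pct_rates`, `pct_overall`.
#' @export
decompose <- function(n_ref, n_cur, e_growth, e_growth_aging) {
  if (!is.finite(n_ref) || n_ref <= 0) {
    stop("domain error: reference count must be positive", call. = FALSE)
  }
  tibble::tibble(
    n_ref = n_ref, n_cur = n_cur,
    e_growth = e_growth, e_growth_aging = e_growth_aging,
    pct_growth = 100 * (e_growth - n_ref) / n_ref,
    pct_aging = 100 * (e_growth_aging - e_growth) / n_ref,
    pct_rates = 100 * (n_cur - e_growth_aging) / n_ref,
    pct_overall = 100 * (n_cur - n_ref) / n_ref
  )
}

#' Percent change between two counts
#'
#' @param v_ref Reference value (> 0); vectorized.
#' @param v_cur Current value.
#' @return `100 * (v_cur - v_ref) / v_ref`.
#' @export
pct_change <- function(v_ref, v_cur) {
  if (any(!is.finite(v_ref) | v_ref <= 0)) {
    stop("domain error: reference value must be positive", call. = FALSE)
  }
  100 * (v_cur - v_ref) / v_ref
}

#' Decompose incidence trends for every group of a burden panel
#'
#' For each group (e.g. by location and/or sex; empty `by` = one global
#' row) the function pools incidence counts and populations over the
#' non-grouped dimensions, derives the reference-year age-specific rates as
#' `count / population * 100,000` and the reference age structure from the
#' reference populations, then chains [expected_counts()] and
#' [decompose()]. Rates are derived from counts and populations rather
#' than read as published rate rows, which keeps numerator and denominator
#' internally consistent. Groups missing age bins (or with a zero
#' reference population/count) are excluded with a reason, never silently.
#'
#' @param cells Burden cells (needs incidence counts at 5-year age bins for
#'   both years).
#' @param pops Population table: `location`, `year`, `sex`, `age_group`,
#'   `population`.
#' @param ref_year,cur_year Reference and current calendar years.
#' @param by Character vector of grouping columns among
#'   `c("location", "sex")`.
#' @return List with `results` (one row per computable group) and
#'   `exclusions`.
#' @export
decompose_panel <- function(cells, pops, ref_year, cur_year,
                            by = character(0)) {
  stopifnot(all(by %in% c("location", "sex")))
  inc <- cells[cells$measure == "incidence" & cells$metric == "count" &
                 cells$age_group %in% gbd_age_bins() &
                 cells$year %in% c(ref_year, cur_year), , drop = FALSE]
  pp <- pops[pops$age_group %in% gbd_age_bins() &
               pops$year %in% c(ref_year, cur_year), , drop = FALSE]
  if (nrow(inc) == 0 || nrow(pp) == 0) {
    stop("insufficiency error: no incidence counts or populations in range",
         call. = FALSE)
  }
  required_bins <- sort(unique(c(inc$age_group, pp$age_group)))

  sum_by <- function(df, value_col) {
    dplyr::summarise(
      dplyr::group_by(df,
                      dplyr::across(dplyr::all_of(c(by, "year", "age_group")))),
      value = sum(.data[[value_col]]), .groups = "drop"
    )
  }
  inc_g <- sum_by(inc, "value")
  pop_g <- sum_by(pp, "population")

  groups <- unique(rbind(inc_g[, by, drop = FALSE], pop_g[, by, drop = FALSE]))
  if (length(by) == 0) groups <- groups[1, , drop = FALSE]

  results <- list()
  exclusions <- list()
  for (i in seq_len(nrow(groups))) {
    g <- groups[i, , drop = FALSE]
    pick <- function(df, yr) {
      sel <- df$year == yr
      for (b in by) sel <- sel & df[[b]] == g[[b]]
      stats::setNames(df$value[sel], df$age_group[sel])
    }
    cnt_ref <- pick(inc_g, ref_year); cnt_cur <- pick(inc_g, cur_year)
    pop_ref <- pick(pop_g, ref_year); pop_cur <- pick(pop_g, cur_year)
    missing_bins <- unique(c(
      setdiff(required_bins, names(cnt_ref)),
      setdiff(required_bins, names(cnt_cur)),
      setdiff(required_bins, names(pop_ref)),
      setdiff(required_bins, names(pop_cur))
    ))
    reason <- NULL
    if (length(missing_bins) > 0) {
      reason <- paste("missing age bins:",
                      paste(sort(missing_bins), collapse = ", "))
    } else if (any(pop_ref == 0)) {
      reason <- "zero reference population in some age bins"
    } else if (sum(cnt_ref) == 0) {
      reason <- "zero reference incidence count"
    }
    if (!is.null(reason)) {
      exclusions[[length(exclusions) + 1]] <-
        tibble::as_tibble(c(as.list(g), list(reason = reason)))
      next
    }
    pop_ref <- pop_ref[required_bins]; pop_cur <- pop_cur[required_bins]
    cnt_ref <- cnt_ref[required_bins]; cnt_cur <- cnt_cur[required_bins]
    rates_ref <- cnt_ref / pop_ref * 1e5
    structure_ref <- pop_ref / sum(pop_ref)
    e <- expected_counts(rates_ref, structure_ref, pop_cur)
    res <- decompose(sum(cnt_ref), sum(cnt_cur),
                     e[["e_growth"]], e[["e_growth_aging"]])
    results[[length(results) + 1]] <- tibble::as_tibble(c(as.list(g), res))
  }
  if (length(results) == 0) {
    stop("insufficiency error: no group computable", call. = FALSE)
  }
  list(
    results = dplyr::bind_rows(results),
    exclusions = if (length(exclusions) > 0) dplyr::bind_rows(exclusions)
    else tibble::tibble(reason = character(0))
  )
}
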