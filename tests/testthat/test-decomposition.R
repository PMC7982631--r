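test_that("expected_counts matches hand arithmetic and its identities", {
  rates <- c(young = 10, old = 100)
  e <- expected_counts(rates, c(young = 0.5, old = 0.5),
                       c(young = 3000, old = 1000))
  expect_equal(unname(e["e_growth"]), 2.2)
  expect_equal(unname(e["e_growth_aging"]), 1.3)

  # unchanged population: both scenarios give the reference expected count
  pop <- c(young = 1000, old = 1000)
  e0 <- expected_counts(rates, pop / sum(pop), pop)
  expect_equal(unname(e0["e_growth"]), unname(e0["e_growth_aging"]))
  expect_equal(unname(e0["e_growth"]), sum(pop * rates) / 1e5)

  # linearity in the current population
  e2 <- expected_counts(rates, c(young = 0.5, old = 0.5),
                        2 * c(young = 3000, old = 1000))
  expect_equal(unname(e2), 2 * unname(e))
  # linearity in the rates
  e3 <- expected_counts(3 * rates, c(young = 0.5, old = 0.5),
                        c(young = 3000, old = 1000))
  expect_equal(unname(e3), 3 * unname(e))
})

test_that("misaligned ages and bad structures are rejected", {
  rates <- c(a = 10, b = 20)
  expect_error(expected_counts(rates, c(a = 0.5, c = 0.5), c(a = 1, b = 1)),
               "alignment error")
  expect_error(expected_counts(rates, c(a = 0.6, b = 0.5), c(a = 1, b = 1)),
               "domain error")
})

test_that("decompose reproduces the published global rows to 2 decimals", {
  printed <- read_table(qcindex_extdata("thyroid_decomposition_global.csv"))
  expected <- list(
    both = c(51.21, 28.74, 88.91, 168.86),
    female = c(51.78, 26.37, 75.05, 153.21),
    male = c(50.64, 34.17, 129.94, 214.75)
  )
  for (i in seq_len(nrow(printed))) {
    r <- decompose(printed$n_1990[i], printed$n_2017[i],
                   printed$e_growth[i], printed$e_growth_aging[i])
    got <- round(c(r$pct_growth, r$pct_aging, r$pct_rates, r$pct_overall), 2)
    expect_equal(got, expected[[printed$sex[i]]], label = printed$sex[i])
  }
})

test_that("no-change decomposition is identically zero and n_ref = 0 fails", {
  r <- decompose(100, 100, 100, 100)
  expect_equal(unlist(r[c("pct_growth", "pct_aging", "pct_rates",
                          "pct_overall")]),
               c(pct_growth = 0, pct_aging = 0, pct_rates = 0,
                 pct_overall = 0))
  expect_error(decompose(0, 10, 5, 5), "domain error")
})

test_that("contributions always sum to the overall change", {
  set.seed(41)
  for (i in 1:200) {
    vals <- runif(4, 1, 1e6)
    r <- decompose(vals[1], vals[2], vals[3], vals[4])
    expect_lt(
      abs(r$pct_growth + r$pct_aging + r$pct_rates - r$pct_overall),
      1e-9 * max(1, abs(r$pct_overall))
    )
  }
})

test_that("pct_change reproduces the published 28-year changes", {
  counts <- read_table(qcindex_extdata("thyroid_global_counts.csv"))
  both <- counts[counts$sex == "both", ]
  printed <- c(prevalence = 177.81, incidence = 168.86, deaths = 86.88,
               dalys = 74.81, ylls = 67.11, ylds = 168.67)
  for (m in names(printed)) {
    v90 <- both$count[both$measure == m & both$year == 1990]
    v17 <- both$count[both$measure == m & both$year == 2017]
    expect_equal(round(pct_change(v90, v17), 2), unname(printed[m]),
                 label = m)
  }
  expect_equal(pct_change(50, 50), 0)
  expect_error(pct_change(0, 10), "domain error")
})

test_that("decompose_panel recovers the analytic truth of a built case", {
  bins <- gbd_age_bins()[c(5, 9, 13)]
  case <- generate_decomposition_case(
    rates_ref = setNames(c(5, 20, 60), bins),
    pop_ref = setNames(c(4e5, 3e5, 1e5), bins),
    pop_cur = setNames(c(5e5, 5e5, 3e5), bins),
    rates_cur = setNames(c(6, 30, 66), bins)
  )
  cells <- dplyr::bind_rows(lapply(bins, function(b) {
    dplyr::bind_rows(
      make_cells(age_group = b, year = 1990L,
                 values = c(incidence = case$pop_ref[[b]] *
                              case$rates_ref[[b]] / 1e5)),
      make_cells(age_group = b, year = 2017L,
                 values = c(incidence = case$pop_cur[[b]] *
                              case$rates_cur[[b]] / 1e5))
    )
  }))
  pops <- tibble::tibble(
    location = "A", sex = "female",
    year = rep(c(1990L, 2017L), each = length(bins)),
    age_group = rep(bins, 2),
    population = c(unname(case$pop_ref), unname(case$pop_cur))
  )
  res <- decompose_panel(cells, pops, 1990, 2017)
  expect_equal(nrow(res$results), 1)
  r <- res$results
  expect_equal(r$n_ref, case$n_ref, tolerance = 1e-9)
  expect_equal(r$pct_growth, case$pct_growth, tolerance = 1e-9)
  expect_equal(r$pct_aging, case$pct_aging, tolerance = 1e-9)
  expect_equal(r$pct_rates, case$pct_rates, tolerance = 1e-9)
  expect_equal(r$pct_overall, case$pct_overall, tolerance = 1e-9)
})

test_that("groups with missing age bins are excluded with a reason", {
  gen <- generate_panel(small_config(seed = 43))
  cells <- gen$cells
  pops <- gen$population
  # drop one age bin of one location in the current year
  drop_bin <- cells$location == "loc_02" & cells$year == 2017 &
    cells$age_group == unique(cells$age_group)[1] & cells$sex == "male"
  res <- decompose_panel(cells[!drop_bin, ], pops, 1990, 2017,
                         by = c("location", "sex"))
  expect_true(any(grepl("missing age bins", res$exclusions$reason)))
  excl <- res$exclusions
  expect_true(any(excl$location == "loc_02" & excl$sex == "male"))
  # every other group is still computed
  expect_equal(nrow(res$results) + nrow(res$exclusions),
               length(unique(cells$location)) * 2)
})

test_that("a global both-sex run over a synthetic panel yields one row", {
  gen <- generate_panel(small_config(n_locations = 2, seed = 47))
  res <- decompose_panel(gen$cells, gen$population, 1990, 2017)
  expect_equal(nrow(res$results), 1)
  r <- res$results
  expect_lt(abs(r$pct_growth + r$pct_aging + r$pct_rates - r$pct_overall),
            1e-9 * max(1, abs(r$pct_overall)))
  # generator encodes growth: the growth contribution must be positive
  expect_gt(r$pct_growth, 0)
})
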