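# Independent oracles and small fixture builders used across the suite.

# PCA oracle: SVD of the standardized data matrix -- a different route than
# the eigendecomposition of the correlation matrix used by fit_qci().
pca_oracle <- function(X) {
  n <- nrow(X)
  means <- colMeans(X)
  sds <- apply(X, 2, sd)
  Z <- sweep(sweep(X, 2, means), 2, sds, `/`)
  sv <- svd(Z)
  v <- sv$v[, 1]
  if (v[which.max(abs(v))] < 0) v <- -v
  list(loadings = v, variance_explained = sv$d[1]^2 / ((n - 1) * ncol(X)))
}

# vectors equal up to a global sign flip
expect_equal_up_to_sign <- function(got, want, tol) {
  dev <- min(max(abs(got - want)), max(abs(got + want)))
  expect_lt(dev, tol)
}

# random observation matrix on realistic ratio scales (4 fixed columns)
random_index_matrix <- function(n) {
  q <- runif(n)
  cbind(
    mir = 0.6 - 0.5 * q + rnorm(n, 0, 0.05),
    daly_prev = 0.5 - 0.3 * q + rnorm(n, 0, 0.05),
    prev_inc = 2 + 10 * q + rnorm(n, 0, 0.5),
    yll_yld = 8 - 6 * q + rnorm(n, 0, 0.3)
  )
}

# one complete stratum of burden cells
make_cells <- function(location = "A", year = 2017L, sex = "female",
                       age_group = "50 to 54",
                       values = c(incidence = 100, prevalence = 800,
                                  deaths = 20, dalys = 560, ylls = 480,
                                  ylds = 80)) {
  tibble::tibble(
    location = location, year = year, sex = sex, age_group = age_group,
    measure = names(values), metric = "count", value = unname(values),
    lower = NA_real_, upper = NA_real_
  )
}

# write a burden table in the default GBD export dialect
write_gbd_fixture <- function(df, path) {
  out <- data.frame(
    measure_name = df$measure, location_name = df$location,
    sex_name = df$sex, age_name = df$age_group, year = df$year,
    metric_name = ifelse(df$metric == "count", "Number", "Rate"),
    val = df$value, lower = df$lower, upper = df$upper
  )
  readr::write_csv(out, path)
  path
}

small_config <- function(n_locations = 4, ...) {
  synthetic_config(n_locations = n_locations,
                   age_bins = gbd_age_bins()[c(6, 10, 14, 18)], ...)
}
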