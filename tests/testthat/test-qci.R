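fit_toy <- function(seed = 31, n = 12) {
  set.seed(seed)
  X <- random_index_matrix(n)
  list(X = X, model = fit_qci(X))
}

iv_from_matrix <- function(X, locations = sprintf("L%d", seq_len(nrow(X)))) {
  out <- tibble::as_tibble(as.data.frame(X))
  out$location <- locations
  out$valid <- TRUE
  out$reason <- NA_character_
  out
}

test_that("two distinct rows give variance explained of one", {
  X <- rbind(c(0.1, 0.4, 9, 5), c(0.3, 0.6, 4, 8))
  colnames(X) <- c("mir", "daly_prev", "prev_inc", "yll_yld")
  model <- fit_qci(X)
  expect_equal(model$variance_explained, 1, tolerance = 1e-12)
})

test_that("loadings match an independent SVD oracle on a small toy matrix", {
  set.seed(7)
  X <- random_index_matrix(5)
  model <- fit_qci(X)
  oracle <- pca_oracle(X)
  expect_equal_up_to_sign(model$loadings, oracle$loadings, 1e-10)
  expect_equal(model$variance_explained, oracle$variance_explained,
               tolerance = 1e-10)
  expect_equal(sum(model$loadings^2), 1, tolerance = 1e-12)
})

test_that("a constant index column is a degenerate-input error naming it", {
  set.seed(7)
  X <- random_index_matrix(6)
  X[, "mir"] <- 0.3
  expect_error(fit_qci(X), "degenerate-input.*mir")
  expect_error(fit_qci(X[1, , drop = FALSE]), "insufficiency")
})

test_that("the oriented score correlates non-positively with MIR", {
  for (seed in 1:5) {
    f <- fit_toy(seed)
    sc <- score_qci(f$model, iv_from_matrix(f$X))
    expect_lte(cor(sc$raw_score, f$X[, "mir"]), 0)
    expect_lte((f$model$orientation * f$model$loadings)[["mir"]], 0)
  }
})

test_that("fitting-set extremes map to 0 and 100 and scoring is reproducible", {
  f <- fit_toy()
  sc <- score_qci(f$model, iv_from_matrix(f$X))
  expect_equal(min(sc$qci), 0)
  expect_equal(max(sc$qci), 100)
  expect_false(any(sc$clipped))
  expect_equal(max(abs(sort(sc$raw_score) -
                         sort(score_qci(f$model, iv_from_matrix(f$X))$raw_score))),
               0)
  # rescale is affine over unclipped scores
  expect_equal(cor(sc$raw_score, sc$qci), 1, tolerance = 1e-12)
})

test_that("out-of-fit extreme vectors are clipped and flagged", {
  f <- fit_toy()
  # drive mir far below anything in the fitting set: better-than-observed care
  extreme <- f$X[1, , drop = FALSE]
  extreme[, "mir"] <- min(f$X[, "mir"]) - 10
  sc <- score_qci(f$model, iv_from_matrix(extreme, "out"))
  expect_true(sc$clipped)
  expect_equal(sc$qci, 100)

  extreme[, "mir"] <- max(f$X[, "mir"]) + 10
  sc <- score_qci(f$model, iv_from_matrix(extreme, "out"))
  expect_true(sc$clipped)
  expect_equal(sc$qci, 0)
})

test_that("raising MIR alone never raises the score", {
  f <- fit_toy()
  base <- f$X[3, , drop = FALSE]
  grid <- do.call(rbind, lapply(seq(0, 0.5, by = 0.05), function(d) {
    r <- base; r[, "mir"] <- r[, "mir"] + d; r
  }))
  sc <- score_qci(f$model, iv_from_matrix(grid))
  expect_true(all(diff(sc$qci) <= 1e-12))
})

test_that("invalid vectors are skipped with an audit record, never scored", {
  f <- fit_toy()
  iv <- iv_from_matrix(f$X)
  iv$valid[2] <- FALSE
  iv$reason[2] <- "zero denominator for mir"
  sc <- score_qci(f$model, iv)
  expect_equal(nrow(sc), nrow(iv) - 1)
  skipped <- attr(sc, "skipped")
  expect_equal(skipped$location, "L2")
})

test_that("model serialization round-trips bit-exactly", {
  f <- fit_toy()
  path <- tempfile(fileext = ".txt")
  write_qci_model(f$model, path)
  back <- read_qci_model(path)
  for (fld in c("means", "sds", "loadings", "orientation",
                "variance_explained", "score_min", "score_max", "fit_n")) {
    expect_identical(unname(back[[fld]]), unname(f$model[[fld]]), label = fld)
  }
  sc1 <- score_qci(f$model, iv_from_matrix(f$X))
  sc2 <- score_qci(back, iv_from_matrix(f$X))
  expect_identical(sc1$qci, sc2$qci)
})

test_that("aggregation scores pooled counts, not averaged scores", {
  gen <- generate_panel(small_config(seed = 17))
  panels <- pivot_panel(gen$cells, "count")$panels
  iv <- compute_indices(panels)
  model <- fit_qci(index_matrix(iv)$matrix)

  # single-stratum aggregate equals the stratum's own score
  one <- panels[5, , drop = FALSE]
  agg1 <- aggregate_qci(model, one, by = c("location", "year", "sex",
                                           "age_group"))
  direct <- score_qci(model, compute_indices(one))
  expect_equal(agg1$qci, direct$qci)

  # two strata with identical measure profiles: aggregate equals each
  twin <- dplyr::bind_rows(one, one)
  twin$location <- c("X", "Y")
  agg2 <- aggregate_qci(model, twin)
  expect_equal(agg2$qci, direct$qci)

  # hand-summed three-stratum aggregate
  three <- panels[1:3, ]
  summed <- three[1, ]
  for (m in gbd_measures()) summed[[m]] <- sum(three[[m]])
  agg3 <- aggregate_qci(model, three)
  by_hand <- score_qci(model, compute_indices(summed))
  expect_equal(agg3$qci, by_hand$qci)
  # and it differs from the average of constituent scores in general
  consts <- score_qci(model, compute_indices(three))
  expect_false(isTRUE(all.equal(agg3$qci, mean(consts$qci))))
})

test_that("aggregating nothing or by unknown columns fails", {
  gen <- generate_panel(small_config(seed = 17))
  panels <- pivot_panel(gen$cells, "count")$panels
  model <- fit_qci(index_matrix(compute_indices(panels))$matrix)
  expect_error(aggregate_qci(model, panels[0, ]), "coverage")
  expect_error(aggregate_qci(model, panels, by = "nope"), "unknown grouping")
})
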