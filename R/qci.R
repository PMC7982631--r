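## Quality of Care Index: first principal component of the four ratios ------

#' Fit the QCI summarization model
#'
#' Standardizes each of the four ratio columns to mean 0 / SD 1 over the
#' fitting set, takes the leading eigenvector of the resulting 4 x 4
#' correlation matrix as the loadings, and orients the component so that
#' the score correlates non-positively with the mortality-to-incidence
#' ratio (higher score = better care). The eigenvector's intrinsic sign
#' ambiguity is first resolved deterministically by making the
#' largest-magnitude loading positive; the orientation flip is then applied
#' on top. Min/max of the oriented score over the fitting set are stored as
#' the 0-100 rescale bounds.
#'
#' If, after orientation, the mortality-to-incidence loading is positive
#' (the data claim higher case fatality loads toward better care), fitting
#' fails loudly rather than deliver an uninterpretable index.
#'
#' @param matrix Numeric matrix from [index_matrix()]: >= 2 rows, the four
#'   ratio columns, each with nonzero variance.
#' @return A `qci_model`: `means`, `sds`, `loadings` (unit norm),
#'   `orientation` (-1/+1), `variance_explained`, `score_min`, `score_max`,
#'   `fit_n`.
#' @export
fit_qci <- function(matrix) {
  X <- as.matrix(matrix)
  if (!all(index_cols() %in% colnames(X))) {
    stop(sprintf("matrix must have columns %s",
                 paste(index_cols(), collapse = ", ")), call. = FALSE)
  }
  X <- X[, index_cols(), drop = FALSE]
  n <- nrow(X)
  if (n < 2) {
    stop("insufficiency error: need at least 2 rows to fit", call. = FALSE)
  }
  means <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  degenerate <- index_cols()[sds == 0 | !is.finite(sds)]
  if (length(degenerate) > 0) {
    stop(sprintf("degenerate-input error: zero variance in index %s",
                 paste(degenerate, collapse = ", ")), call. = FALSE)
  }
  Z <- sweep(sweep(X, 2, means), 2, sds, `/`)
  C <- crossprod(Z) / (n - 1)
  eig <- eigen(C, symmetric = TRUE)
  v <- eig$vectors[, 1]
  names(v) <- index_cols()
  # deterministic sign: largest-magnitude loading positive
  if (v[which.max(abs(v))] < 0) v <- -v
  raw <- drop(Z %*% v)
  r_mir <- suppressWarnings(stats::cor(raw, X[, "mir"]))
  orientation <- if (is.finite(r_mir) && r_mir > 0) -1 else 1
  if ((orientation * v)[["mir"]] > 0) {
    stop(paste("orientation error: mortality-to-incidence ratio loads",
               "positively on the oriented component; the fitted index",
               "would not be interpretable as care quality"), call. = FALSE)
  }
  scores <- orientation * raw
  model <- list(
    means = means, sds = sds, loadings = v, orientation = orientation,
    variance_explained = eig$values[1] / ncol(X),
    score_min = min(scores), score_max = max(scores), fit_n = n
  )
  stopifnot(abs(sum(v^2) - 1) < 1e-12, model$score_min < model$score_max)
  class(model) <- "qci_model"
  model
}

#' @export
print.qci_model <- function(x, ...) {
  cat("QCI model (first principal component of 4 burden ratios)\n")
  cat(sprintf("  fit on %d strata; variance explained by PC1: %.2f%%\n",
              x$fit_n, 100 * x$variance_explained))
  cat("  oriented loadings:\n")
  print(round(x$orientation * x$loadings, 4))
  cat(sprintf("  score bounds: [%.4f, %.4f]\n", x$score_min, x$score_max))
  invisible(x)
}

#' Score index vectors on the 0-100 QCI scale
#'
#' Applies the fitted standardization and loadings to each valid index
#' vector, then maps the oriented raw score affinely to 0-100 using the
#' fitting-set bounds. Out-of-fit scores falling outside the bounds are
#' clipped and flagged. Invalid vectors are never scored: they are skipped
#' and returned in the `"skipped"` attribute for audit.
#'
#' @param model A fitted [fit_qci()] model.
#' @param vectors Tibble from [compute_indices()] (a `valid` column is
#'   honoured when present).
#' @return Tibble: key columns, `raw_score`, `qci` in `[0, 100]`,
#'   `clipped`; attribute `"skipped"` holds the unscored rows.
#' @export
score_qci <- function(model, vectors) {
  stopifnot(inherits(model, "qci_model"))
  vectors <- tibble::as_tibble(vectors)
  valid <- if ("valid" %in% names(vectors)) vectors$valid else
    rep(TRUE, nrow(vectors))
  ok <- vectors[valid, , drop = FALSE]
  skipped <- vectors[!valid, , drop = FALSE]
  X <- as.matrix(ok[, index_cols()])
  Z <- sweep(sweep(X, 2, model$means), 2, model$sds, `/`)
  raw <- model$orientation * drop(Z %*% model$loadings)
  span <- model$score_max - model$score_min
  qci_unclipped <- 100 * (raw - model$score_min) / span
  keys <- ok[, setdiff(names(ok),
                       c(index_cols(), gbd_measures(), "valid", "reason")),
             drop = FALSE]
  out <- tibble::as_tibble(keys)
  out$raw_score <- raw
  out$qci <- pmin(pmax(qci_unclipped, 0), 100)
  out$clipped <- raw < model$score_min | raw > model$score_max
  attr(out, "skipped") <- skipped
  out
}

#' Aggregate QCI at a coarser scale by pooling counts
#'
#' The QCI of an aggregate (a location over the whole study period, a
#' global age group, ...) is computed by summing the six measure counts over
#' the constituent strata, recomputing the four ratios on the summed
#' counts, and scoring with the already-fitted model -- never by averaging
#' constituent QCI scores.
#'
#' @param model A fitted [fit_qci()] model.
#' @param panels Measure panels (finest strata, counts).
#' @param by Character vector of key columns to retain (empty = one global
#'   row pooling everything).
#' @return Tibble of scores as from [score_qci()], one row per group.
#' @export
aggregate_qci <- function(model, panels, by = character(0)) {
  if (nrow(panels) == 0) {
    stop("coverage error: no constituent strata to aggregate", call. = FALSE)
  }
  bad <- setdiff(by, names(panels))
  if (length(bad) > 0) {
    stop(sprintf("unknown grouping column(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  agg <- dplyr::summarise(
    dplyr::group_by(panels, dplyr::across(dplyr::all_of(by))),
    dplyr::across(dplyr::all_of(gbd_measures()), sum),
    .groups = "drop"
  )
  score_qci(model, compute_indices(agg))
}

## Model serialization: flat key=value text, exact round trip ----------------

fmt17 <- function(x) sprintf("%.17g", x)

#' Write a QCI model to a flat key-value text file
#'
#' Values are written with 17 significant digits, so [read_qci_model()]
#' restores every double bit-exactly.
#'
#' @param model A `qci_model`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_qci_model <- function(model, path) {
  writeLines(qci_model_lines(model), path)
  invisible(path)
}

qci_model_lines <- function(model) {
  stopifnot(inherits(model, "qci_model"))
  c(
    paste0("means.", index_cols(), "=", fmt17(model$means)),
    paste0("sds.", index_cols(), "=", fmt17(model$sds)),
    paste0("loadings.", index_cols(), "=", fmt17(model$loadings)),
    paste0("orientation=", format(model$orientation)),
    paste0("variance_explained=", fmt17(model$variance_explained)),
    paste0("score_min=", fmt17(model$score_min)),
    paste0("score_max=", fmt17(model$score_max)),
    paste0("fit_n=", format(model$fit_n))
  )
}

#' Read a QCI model written by [write_qci_model()]
#'
#' @param path Path to the key-value file.
#' @return A `qci_model`.
#' @export
read_qci_model <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, `[`, character(1), 2)
  get_vec <- function(prefix) {
    stats::setNames(
      as.numeric(vals[match(paste0(prefix, ".", index_cols()), keys)]),
      index_cols()
    )
  }
  scalar <- function(key) as.numeric(vals[match(key, keys)])
  model <- list(
    means = get_vec("means"), sds = get_vec("sds"),
    loadings = get_vec("loadings"),
    orientation = scalar("orientation"),
    variance_explained = scalar("variance_explained"),
    score_min = scalar("score_min"), score_max = scalar("score_max"),
    fit_n = as.integer(scalar("fit_n"))
  )
  class(model) <- "qci_model"
  model
}
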