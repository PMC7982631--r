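## End-to-end orchestration --------------------------------------------------

#' Pipeline configuration
#'
#' Exactly one data source is active: either `synthetic = TRUE` with a
#' generator config, or paths to a burden CSV and a population CSV.
#'
#' @param out_dir Output directory (created if absent).
#' @param synthetic Generate the input panel instead of reading files.
#' @param synthetic_config Generator settings, see [synthetic_config()].
#' @param burden_path,population_path Input CSVs when `synthetic = FALSE`.
#' @param metric Metric pivoted for the ratio pipeline (counts are
#'   canonical).
#' @param seed Integer seed recorded in every output's provenance header;
#'   overrides the generator config's seed so one value governs the run.
#' @param rounding Decimals used by [report_summary()] (report layer only;
#'   stored tables keep full precision).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            synthetic = TRUE,
                            synthetic_config = qcindex::synthetic_config(),
                            burden_path = NULL,
                            population_path = NULL,
                            metric = "count",
                            seed = 1L,
                            rounding = 2L) {
  if (synthetic && (!is.null(burden_path) || !is.null(population_path))) {
    stop("config error: choose either synthetic data or input paths, not both",
         call. = FALSE)
  }
  if (!synthetic && (is.null(burden_path) || is.null(population_path))) {
    stop("config error: burden_path and population_path are both required",
         call. = FALSE)
  }
  cfg <- list(
    out_dir = out_dir, synthetic = synthetic,
    synthetic_config = synthetic_config,
    burden_path = burden_path, population_path = population_path,
    metric = metric, seed = as.integer(seed), rounding = as.integer(rounding)
  )
  class(cfg) <- "pipeline_config"
  cfg
}

run_stage <- function(name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  message(sprintf("[%s] done in %.2fs", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the full QCI pipeline
#'
#' Stages: obtain data (generate or read), pivot to measure panels, compute
#' the four ratios, fit the QCI model on the finest strata (5-year age bins
#' only; aggregate age rows are excluded from fitting), score the finest
#' strata, build aggregate scores (per location pooled over the study
#' period, and per location x sex for the disparity analysis), the
#' gender-disparity table and scatter pairs, and the incidence
#' decomposition (overall and per sex). Every output CSV carries a
#' provenance header with the config hash and seed; a manifest lists all
#' outputs with row counts. Reruns with an identical config are
#' byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the run manifest: `config`, `config_hash`, `outputs`
#'   (file table), and the in-memory `tables`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  # hash the scientific configuration only: where outputs land is not part
  # of what was computed
  cfg_hash <- rlang::hash(config[setdiff(names(config), "out_dir")])
  prov <- sprintf("qcindex run config_hash=%s seed=%d", cfg_hash, config$seed)

  truth <- NULL
  if (config$synthetic) {
    gen_cfg <- config$synthetic_config
    gen_cfg$seed <- config$seed
    gen <- run_stage("generate", generate_panel(gen_cfg))
    cells <- gen$cells
    pops <- gen$population
    truth <- gen$truth
  } else {
    cells <- run_stage("read_burden", read_gbd_csv(config$burden_path))
    pops <- run_stage("read_population", read_table(config$population_path))
  }

  piv <- run_stage("pivot", pivot_panel(cells, config$metric))
  panels <- piv$panels[piv$panels$age_group %in% gbd_age_bins(), , drop = FALSE]
  if (nrow(panels) == 0) {
    stop("stage 'pivot' failed: no complete finest-level strata", call. = FALSE)
  }

  indices <- run_stage("indices", compute_indices(panels))
  mat <- run_stage("matrix", index_matrix(indices))
  model <- run_stage("fit", fit_qci(mat$matrix))
  scores <- run_stage("score", score_qci(model, indices))

  agg <- run_stage("aggregate", dplyr::bind_rows(
    location = aggregate_qci(model, panels, by = "location"),
    location_sex = aggregate_qci(model, panels, by = c("location", "sex")),
    age_sex = aggregate_qci(model, panels, by = c("age_group", "sex")),
    global = aggregate_qci(model, panels),
    .id = "scale"
  ))

  gdr_loc <- run_stage(
    "gdr", gdr_table(agg[agg$scale == "location_sex",
                         c("location", "sex", "raw_score", "qci", "clipped")])
  )
  pairs <- run_stage("scatter", scatter_pairs(gdr_loc$records))

  years <- sort(unique(panels$year))
  dec <- run_stage("decompose", {
    both <- decompose_panel(cells, pops, years[1], years[length(years)])
    by_sex <- decompose_panel(cells, pops, years[1], years[length(years)],
                              by = "sex")
    both$results$sex <- "both"
    list(
      results = dplyr::bind_rows(both$results, by_sex$results),
      exclusions = dplyr::bind_rows(both$exclusions, by_sex$exclusions)
    )
  })

  exclusions <- dplyr::bind_rows(
    pivot = piv$exclusions,
    indices = tibble::as_tibble(
      indices[!indices$valid, c(stratum_cols(), "reason")]),
    gdr = gdr_loc$exclusions,
    decomposition = dec$exclusions,
    .id = "stage"
  )

  tables <- list(
    indices = indices, qci_scores = scores, qci_aggregates = agg,
    gdr = gdr_loc$records, scatter_pairs = pairs,
    decomposition = dec$results, exclusions = exclusions
  )
  paths <- c(
    indices = "indices.csv", qci_model = "qci_model.txt",
    qci_scores = "qci_scores.csv", qci_aggregates = "qci_aggregates.csv",
    gdr = "gdr.csv", scatter_pairs = "scatter_pairs.csv",
    decomposition = "decomposition.csv", exclusions = "exclusions.csv"
  )
  for (nm in names(tables)) {
    write_table(tables[[nm]], file.path(config$out_dir, paths[[nm]]),
                comment = prov)
  }
  model_path <- file.path(config$out_dir, paths[["qci_model"]])
  writeLines(c(paste("#", prov), qci_model_lines(model)), model_path)

  outputs <- tibble::tibble(
    output = names(paths),
    path = unname(paths),
    rows = vapply(names(paths), function(nm) {
      if (nm == "qci_model") NA_integer_ else nrow(tables[[nm]])
    }, integer(1))
  )
  manifest <- tibble::tibble(config_hash = cfg_hash, seed = config$seed,
                             output = outputs$output, path = outputs$path,
                             rows = outputs$rows)
  write_table(manifest, file.path(config$out_dir, "manifest.csv"),
              comment = prov)

  invisible(list(config = config, config_hash = cfg_hash, outputs = outputs,
                 tables = tables, model = model, truth = truth))
}

#' Print a human-readable summary of a pipeline run
#'
#' Shows the variance explained by the first component, global and
#' per-location QCI (top and bottom), gender-disparity extremes, and the
#' decomposition rows, rounded at the configured report precision.
#'
#' @param manifest The list returned by [run_pipeline()].
#' @return Invisibly, `manifest`.
#' @export
report_summary <- function(manifest) {
  r <- manifest$config$rounding
  t <- manifest$tables
  cat(sprintf("qcindex run %s (seed %d)\n",
              manifest$config_hash, manifest$config$seed))
  cat(sprintf("PC1 variance explained: %s%%\n",
              format(round(100 * manifest$model$variance_explained, r),
                     nsmall = r)))
  glob <- t$qci_aggregates[t$qci_aggregates$scale == "global", ]
  cat(sprintf("Global QCI: %s\n", format(round(glob$qci, r), nsmall = r)))
  loc <- t$qci_aggregates[t$qci_aggregates$scale == "location", ]
  loc <- loc[order(-loc$qci), ]
  cat("QCI by location (best to worst):\n")
  for (i in seq_len(nrow(loc))) {
    cat(sprintf("  %s  %s\n", loc$location[i],
                format(round(loc$qci[i], r), nsmall = r)))
  }
  g <- t$gdr[!t$gdr$undefined, ]
  if (nrow(g) > 0) {
    cat(sprintf("GDR range: %s (%s) to %s (%s)\n",
                format(round(min(g$gdr), r), nsmall = r),
                g$location[which.min(g$gdr)],
                format(round(max(g$gdr), r), nsmall = r),
                g$location[which.max(g$gdr)]))
  }
  cat("Incidence decomposition (% of reference-year count):\n")
  d <- t$decomposition
  for (i in seq_len(nrow(d))) {
    cat(sprintf(
      "  %s: growth %s, aging %s, rates %s, overall %s\n", d$sex[i],
      format(round(d$pct_growth[i], r), nsmall = r),
      format(round(d$pct_aging[i], r), nsmall = r),
      format(round(d$pct_rates[i], r), nsmall = r),
      format(round(d$pct_overall[i], r), nsmall = r)
    ))
  }
  invisible(manifest)
}
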