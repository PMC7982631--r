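## Canonical vocabularies for GBD-results-style tables ------------------------

#' Six burden measures handled by the package
#'
#' Canonical (lower-case) measure labels, in the fixed column order used by
#' pivoted panels and all downstream tables.
#'
#' @return Character vector of length 6.
#' @export
gbd_measures <- function() {
  c("incidence", "prevalence", "deaths", "dalys", "ylls", "ylds")
}

#' Five-year age-bin labels
#'
#' The standard GBD 5-year age groups `"0 to 4"` ... `"90 to 94"` plus
#' `"95 plus"`.
#'
#' @return Character vector of 20 ordered age-bin labels.
#' @export
gbd_age_bins <- function() {
  c(sprintf("%d to %d", seq(0, 90, by = 5), seq(4, 94, by = 5)), "95 plus")
}

# Aggregate age labels accepted on read but excluded from index fitting.
gbd_age_aggregates <- function() c("All Ages", "Age-standardized")

gbd_age_vocab <- function() c(gbd_age_bins(), gbd_age_aggregates())

# Long GBD export labels -> canonical measure names. Matching is
# case-insensitive on the short names as well.
measure_alias <- c(
  "incidence"  = "incidence",
  "prevalence" = "prevalence",
  "deaths"     = "deaths",
  "dalys"      = "dalys",
  "ylls"       = "ylls",
  "ylds"       = "ylds",
  "dalys (disability-adjusted life years)" = "dalys",
  "ylls (years of life lost)"              = "ylls",
  "ylds (years lived with disability)"     = "ylds"
)

sex_alias <- c("female" = "female", "male" = "male", "both" = "both")

metric_alias <- c(
  "count" = "count", "number" = "count",
  "rate" = "rate_per_100k", "rate_per_100k" = "rate_per_100k"
)

#' Default column dialect of the GBD results-tool export
#'
#' Maps the package's canonical field names to the column names found in a
#' GBD results-tool CSV export. Pass a modified copy to [read_gbd_csv()] for
#' files with other headers. `lower` and `upper` are optional columns.
#'
#' @return Named character vector (canonical field -> column name).
#' @export
gbd_dialect <- function() {
  c(
    measure   = "measure_name",
    location  = "location_name",
    sex       = "sex_name",
    age_group = "age_name",
    year      = "year",
    metric    = "metric_name",
    value     = "val",
    lower     = "lower",
    upper     = "upper"
  )
}

match_vocab <- function(x, alias, what) {
  idx <- match(tolower(trimws(x)), names(alias))
  bad <- which(is.na(idx))
  if (length(bad) > 0) {
    stop(sprintf(
      "vocabulary error: unknown %s label '%s' at row %d",
      what, x[bad[1]], bad[1]
    ), call. = FALSE)
  }
  unname(alias[idx])
}

## Reading --------------------------------------------------------------------

#' Read a GBD-results-style burden CSV
#'
#' Parses a comma-separated burden table (optionally gzip-compressed) into a
#' tibble of burden cells with canonical columns `location`, `year`, `sex`,
#' `age_group`, `measure`, `metric`, `value`, `lower`, `upper`. Measure, sex,
#' age-group, and metric labels are validated against the package
#' vocabularies; unknown labels, missing required columns, and negative
#' values are errors. When uncertainty bounds are present they must bracket
#' the value.
#'
#' @param path Path to a CSV (or .csv.gz) file.
#' @param dialect Named character vector mapping canonical field names to
#'   column names; see [gbd_dialect()].
#' @return Tibble of burden cells, one row per input row.
#' @export
read_gbd_csv <- function(path, dialect = gbd_dialect()) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         comment = "#")
  required <- c("measure", "location", "sex", "age_group", "year",
                "metric", "value")
  for (field in required) {
    col <- dialect[[field]]
    if (is.null(col) || !col %in% names(raw)) {
      stop(sprintf("schema error: missing required column '%s' (field '%s')",
                   if (is.null(col)) field else col, field), call. = FALSE)
    }
  }
  n <- nrow(raw)
  get_opt <- function(field) {
    col <- dialect[[field]]
    if (!is.null(col) && col %in% names(raw)) as.numeric(raw[[col]])
    else rep(NA_real_, n)
  }
  cells <- tibble::tibble(
    location  = as.character(raw[[dialect[["location"]]]]),
    year      = as.integer(raw[[dialect[["year"]]]]),
    sex       = character(n),
    age_group = as.character(raw[[dialect[["age_group"]]]]),
    measure   = character(n),
    metric    = character(n),
    value     = as.numeric(raw[[dialect[["value"]]]]),
    lower     = get_opt("lower"),
    upper     = get_opt("upper")
  )
  if (n == 0) return(cells)

  cells$measure <- match_vocab(raw[[dialect[["measure"]]]], measure_alias, "measure")
  cells$sex     <- match_vocab(raw[[dialect[["sex"]]]], sex_alias, "sex")
  cells$metric  <- match_vocab(raw[[dialect[["metric"]]]], metric_alias, "metric")
  bad_age <- which(!cells$age_group %in% gbd_age_vocab())
  if (length(bad_age) > 0) {
    stop(sprintf("vocabulary error: unknown age_group label '%s' at row %d",
                 cells$age_group[bad_age[1]], bad_age[1]), call. = FALSE)
  }
  neg <- which(is.na(cells$value) | cells$value < 0)
  if (length(neg) > 0) {
    stop(sprintf("domain error: missing or negative value at row %d", neg[1]),
         call. = FALSE)
  }
  has_bounds <- !is.na(cells$lower) & !is.na(cells$upper)
  bad_b <- which(has_bounds &
                   (cells$lower > cells$value | cells$value > cells$upper))
  if (length(bad_b) > 0) {
    stop(sprintf("domain error: value outside [lower, upper] at row %d",
                 bad_b[1]), call. = FALSE)
  }
  cells
}

## Pivoting -------------------------------------------------------------------

stratum_cols <- function() c("location", "year", "sex", "age_group")

#' Pivot burden cells into per-stratum measure panels
#'
#' Filters cells to one metric and spreads the six measures into columns,
#' one row per (location, year, sex, age_group) stratum. Strata missing any
#' of the six measures are never silently dropped: they are returned in an
#' exclusion table with the reason naming the missing measures. Duplicate
#' (stratum, measure) pairs are an integrity error.
#'
#' A warning is raised when `dalys` deviates from `ylls + ylds` by more than
#' 0.1% relative in any complete stratum (source rounding can break exact
#' equality, larger deviations indicate inconsistent input).
#'
#' @param cells Tibble of burden cells as returned by [read_gbd_csv()].
#' @param metric `"count"` (canonical for all downstream ratios) or
#'   `"rate_per_100k"`.
#' @return List with `panels` (complete strata, six measure columns) and
#'   `exclusions` (stratum keys + `reason`).
#' @export
pivot_panel <- function(cells, metric = c("count", "rate_per_100k")) {
  metric <- match.arg(metric)
  keep <- cells[cells$metric == metric, , drop = FALSE]
  dup <- dplyr::count(keep,
                      dplyr::across(dplyr::all_of(c(stratum_cols(), "measure"))))
  dup <- dup[dup$n > 1, , drop = FALSE]
  if (nrow(dup) > 0) {
    labs <- utils::head(sprintf("%s/%s/%s/%s/%s", dup$location, dup$year,
                                dup$sex, dup$age_group, dup$measure), 5)
    stop(sprintf("integrity error: duplicate (stratum, measure) pairs: %s",
                 paste(labs, collapse = "; ")), call. = FALSE)
  }
  wide <- tidyr::pivot_wider(
    keep[, c(stratum_cols(), "measure", "value")],
    names_from = "measure", values_from = "value"
  )
  for (m in setdiff(gbd_measures(), names(wide))) wide[[m]] <- NA_real_
  wide <- wide[, c(stratum_cols(), gbd_measures())]

  miss <- is.na(as.matrix(wide[, gbd_measures()]))
  incomplete <- rowSums(miss) > 0
  exclusions <- wide[incomplete, stratum_cols()]
  exclusions$reason <- vapply(which(incomplete), function(i) {
    paste("missing", paste(gbd_measures()[miss[i, ]], collapse = ", "))
  }, character(1))
  panels <- wide[!incomplete, , drop = FALSE]

  if (nrow(panels) > 0) {
    rel <- abs(panels$dalys - (panels$ylls + panels$ylds)) /
      pmax(panels$dalys, .Machine$double.eps)
    n_bad <- sum(rel > 0.001)
    if (n_bad > 0) {
      warning(sprintf(
        "dalys deviates from ylls + ylds by > 0.1%% relative in %d strata",
        n_bad), call. = FALSE)
    }
  }
  list(panels = panels, exclusions = exclusions)
}

## Writing --------------------------------------------------------------------

#' Write a result table to CSV at full precision
#'
#' Columns are written in their current (documented) order; reals keep the
#' shortest representation that round-trips exactly, so
#' `read_table(write_table(x))` returns identical values. An optional
#' provenance comment is prepended as `#`-prefixed lines, which
#' [read_table()] skips.
#'
#' @param records Data frame to write (may have zero rows: header only).
#' @param path Output file path.
#' @param comment Optional character vector of provenance lines (written
#'   with a leading `"# "`).
#' @return Invisibly, `path`.
#' @export
write_table <- function(records, path, comment = NULL) {
  if (!is.null(comment)) {
    writeLines(paste("#", comment), path)
    readr::write_csv(records, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_csv(records, path)
  }
  invisible(path)
}

#' Path to a bundled data file
#'
#' The package ships the published all-age global thyroid-cancer counts
#' for 1990 and 2017 (`thyroid_global_counts.csv`) and the global
#' incidence-decomposition counts (`thyroid_decomposition_global.csv`)
#' from the GBD 1990-2017 estimates, as printed in the published summary
#' tables.
#'
#' @param file File name under `extdata/`; empty lists the available
#'   files.
#' @return Full path (or file listing).
#' @export
qcindex_extdata <- function(file = "") {
  out <- system.file("extdata", file, package = "qcindex", mustWork = FALSE)
  if (!nzchar(out)) {
    stop(sprintf("no bundled file '%s'", file), call. = FALSE)
  }
  out
}

#' Read a table written by [write_table()]
#'
#' @param path CSV path.
#' @return Tibble with the stored values at full precision.
#' @export
read_table <- function(path) {
  # base strtod parsing restores write_csv's shortest-round-trip decimals
  # bit-exactly
  tibble::as_tibble(utils::read.csv(path, comment.char = "#",
                                    check.names = FALSE))
}
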