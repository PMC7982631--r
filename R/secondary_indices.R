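## Four secondary burden ratios per stratum ---------------------------------

index_cols <- function() c("mir", "daly_prev", "prev_inc", "yll_yld")

#' Compute the four secondary care-quality ratios per stratum
#'
#' Adds to each measure panel row the mortality-to-incidence ratio
#' (`mir = deaths / incidence`), the DALY-to-prevalence ratio
#' (`daly_prev = dalys / prevalence`), the prevalence-to-incidence ratio
#' (`prev_inc = prevalence / incidence`), and the YLL-to-YLD ratio
#' (`yll_yld = ylls / ylds`). Ratios are computed from counts; within a
#' stratum count ratios equal rate ratios, and counts avoid report-rounding
#' artifacts in published rates.
#'
#' A zero denominator never raises an error: the affected ratios are set to
#' `NA`, `valid` is `FALSE`, and `reason` names the undefined ratio(s).
#' Zero numerators simply yield 0. Strata flagged invalid are excluded from
#' model fitting downstream but retained here for audit.
#'
#' @param panels Data frame with the six measure columns of
#'   [gbd_measures()]; any other columns are carried through as stratum
#'   keys.
#' @return Tibble: key columns, the four ratio columns, `valid`, `reason`.
#' @export
compute_indices <- function(panels) {
  missing_cols <- setdiff(gbd_measures(), names(panels))
  if (length(missing_cols) > 0) {
    stop(sprintf("panel is missing measure column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  out <- tibble::as_tibble(panels)
  safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  out$mir       <- safe_div(out$deaths, out$incidence)
  out$daly_prev <- safe_div(out$dalys, out$prevalence)
  out$prev_inc  <- safe_div(out$prevalence, out$incidence)
  out$yll_yld   <- safe_div(out$ylls, out$ylds)

  undef <- cbind(
    mir = out$incidence == 0, daly_prev = out$prevalence == 0,
    prev_inc = out$incidence == 0, yll_yld = out$ylds == 0
  )
  out$valid <- rowSums(undef) == 0
  out$reason <- NA_character_
  bad <- which(!out$valid)
  if (length(bad) > 0) {
    out$reason[bad] <- vapply(bad, function(i) {
      paste("zero denominator for",
            paste(index_cols()[undef[i, ]], collapse = ", "))
    }, character(1))
  }
  out
}

#' Assemble the observation matrix for index summarization
#'
#' Keeps only valid index vectors and returns the n x 4 matrix in the fixed
#' column order `mir, daly_prev, prev_inc, yll_yld`, together with the key
#' columns row-aligned to the matrix.
#'
#' @param vectors Tibble from [compute_indices()].
#' @return List with `matrix` (numeric, 4 columns) and `keys` (tibble, one
#'   row per matrix row).
#' @export
index_matrix <- function(vectors) {
  ok <- vectors[vectors$valid, , drop = FALSE]
  if (nrow(ok) < 2) {
    stop(sprintf("insufficiency error: %d valid index vector(s), need >= 2",
                 nrow(ok)), call. = FALSE)
  }
  X <- as.matrix(ok[, index_cols()])
  keys <- ok[, setdiff(names(ok),
                       c(index_cols(), gbd_measures(), "valid", "reason")),
             drop = FALSE]
  list(matrix = X, keys = keys)
}
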