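## Gender disparity ratio on the QCI scale ----------------------------------

#' Gender disparity ratio for one matched pair of scores
#'
#' `gdr = qci_female / qci_male`; a value of 1 indicates parity, above 1
#' better care for women. Both scores must describe the same stratum apart
#' from sex. A male score of exactly 0 (a rescale-endpoint artifact) yields
#' an undefined ratio, flagged rather than infinite.
#'
#' @param female,male Single-row score tibbles from [score_qci()], sharing
#'   every key column except `sex`.
#' @return One-row tibble: shared keys, `qci_female`, `qci_male`, `gdr`,
#'   `undefined`.
#' @export
compute_gdr <- function(female, male) {
  stopifnot(nrow(female) == 1, nrow(male) == 1)
  keys <- setdiff(intersect(names(female), names(male)),
                  c("sex", "raw_score", "qci", "clipped"))
  for (k in keys) {
    if (!identical(female[[k]], male[[k]])) {
      stop(sprintf("pairing error: key '%s' differs (%s vs %s)",
                   k, female[[k]], male[[k]]), call. = FALSE)
    }
  }
  out <- tibble::as_tibble(female[, keys, drop = FALSE])
  out$qci_female <- female$qci
  out$qci_male <- male$qci
  out$undefined <- male$qci == 0
  out$gdr <- ifelse(out$undefined, NA_real_, female$qci / male$qci)
  out
}

#' Gender disparity ratio table over a score set
#'
#' Pairs female and male scores on all remaining key columns. Keys present
#' for only one sex are never silently dropped: they are reported in the
#' exclusion table.
#'
#' @param scores Score tibble from [score_qci()] containing a `sex` column
#'   with values `"female"` / `"male"`.
#' @return List with `records` (keys, `qci_female`, `qci_male`, `gdr`,
#'   `undefined`) and `exclusions` (unpaired keys + `reason`).
#' @export
gdr_table <- function(scores) {
  if (!"sex" %in% names(scores)) {
    stop("scores must carry a 'sex' column", call. = FALSE)
  }
  keys <- setdiff(names(scores), c("sex", "raw_score", "qci", "clipped"))
  wide <- tidyr::pivot_wider(
    scores[, c(keys, "sex", "qci")],
    names_from = "sex", values_from = "qci", names_prefix = "qci_"
  )
  for (col in c("qci_female", "qci_male")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  paired <- !is.na(wide$qci_female) & !is.na(wide$qci_male)
  records <- wide[paired, c(keys, "qci_female", "qci_male"), drop = FALSE]
  records$undefined <- records$qci_male == 0
  records$gdr <- ifelse(records$undefined, NA_real_,
                        records$qci_female / records$qci_male)
  exclusions <- wide[!paired, keys, drop = FALSE]
  exclusions$reason <- as.character(ifelse(is.na(wide$qci_female[!paired]),
                                           "missing female score",
                                           "missing male score"))
  list(records = records, exclusions = exclusions)
}

#' Paired female/male QCI table for scatter comparison
#'
#' Two locations can share a near-one disparity ratio while sitting at very
#' different absolute quality; this table keeps both coordinates so they
#' can be compared directly. Rows are sorted deterministically by location
#' (then any remaining keys); values are passed through unaltered.
#'
#' @param records `records` tibble from [gdr_table()].
#' @return Tibble sorted by location: keys, `qci_female`, `qci_male`,
#'   `gdr`.
#' @export
scatter_pairs <- function(records) {
  if (nrow(records) == 0) {
    stop("no gender-disparity records to pair", call. = FALSE)
  }
  keys <- setdiff(names(records),
                  c("qci_female", "qci_male", "gdr", "undefined"))
  ord <- do.call(order, records[, keys, drop = FALSE])
  records[ord, c(keys, "qci_female", "qci_male", "gdr"), drop = FALSE]
}
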