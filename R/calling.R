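#' Infection-cutoff threshold from uninfected-control intensities
#'
#' The infection cutoff is the 99.9th percentile (by default) of the median
#' nuclear GFP intensities of the uninfected control, computed with linear
#' interpolation between order statistics (Hyndman–Fan type 7, the default of
#' the mainstream numeric stacks). By construction the expected fraction of
#' control nuclei above the cutoff is `1 - percentile/100` (0.001 at the
#' default), which is the design false-positive rate of the caller.
#'
#' Controls are pooled per plate: pass all control-well nuclei of one plate.
#'
#' @param control_intensities numeric vector of control-nucleus median
#'   intensities (arbitrary units).
#' @param percentile percentile in (0, 100); default 99.9.
#' @param min_control_nuclei QC floor on the number of control nuclei
#'   (default 100) below which the percentile is too unstable to trust.
#' @return the threshold (scalar).
#' @examples
#' compute_threshold(seq_len(1000))  # 999.001
#' @export
compute_threshold <- function(control_intensities, percentile = 99.9,
                              min_control_nuclei = 100) {
  x <- control_intensities[!is.na(control_intensities)]
  if (length(x) == 0L) {
    stop("no control intensities supplied", call. = FALSE)
  }
  if (length(x) < min_control_nuclei) {
    stop(sprintf("QC: only %d control nuclei (< %d); threshold would be unstable",
                 length(x), min_control_nuclei), call. = FALSE)
  }
  if (!is.numeric(percentile) || length(percentile) != 1L ||
      percentile <= 0 || percentile >= 100) {
    stop("`percentile` must lie strictly between 0 and 100", call. = FALSE)
  }
  unname(stats::quantile(x, percentile / 100, type = 7, names = FALSE))
}

#' Call infected nuclei and compute per-well infection indices
#'
#' Labels every nucleus with intensity strictly above `threshold` as infected
#' (ties count as uninfected) and summarizes each well as
#' `infection_index = infected / n_nuclei`. Wells with fewer than `min_nuclei`
#' nuclei are QC-flagged and should be excluded from downstream statistics;
#' their index is still reported. A well known to the caller but absent from
#' `records` has no nuclei: its index is undefined and must be treated as
#' missing, never as 0.
#'
#' @param records per-nucleus tibble with at least `well` and `median_gfp`
#'   columns; any of `plate`, `population_id`, `parental_id`, `branch`,
#'   `tech_rep`, `week`, `condition` present are carried through.
#' @param threshold intensity cutoff from [compute_threshold()] for the
#'   matching plate.
#' @param min_nuclei per-well QC floor (default 50).
#' @return a tibble, one row per well: metadata, `n_nuclei`, `n_infected`,
#'   `infection_index`, `qc_flag` (TRUE = too few nuclei). The threshold is
#'   attached as attribute `"threshold"`.
#' @export
call_and_index <- function(records, threshold, min_nuclei = 50) {
  stopifnot(is.data.frame(records), all(c("well", "median_gfp") %in% names(records)))
  .assert_scalar_number(threshold, "threshold")
  meta_cols <- intersect(c("plate", "well", "population_id", "parental_id",
                           "branch", "tech_rep", "week", "condition"),
                         names(records))
  records$.infected <- records$median_gfp > threshold
  out <- records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(meta_cols))) |>
    dplyr::summarise(n_nuclei = dplyr::n(),
                     n_infected = sum(.data$.infected),
                     .groups = "drop") |>
    dplyr::mutate(infection_index = .data$n_infected / .data$n_nuclei,
                  qc_flag = .data$n_nuclei < min_nuclei)
  attr(out, "threshold") <- threshold
  out
}

#' Run the full calling pipeline on a measurement table
#'
#' Convenience wrapper: for each plate, pools that plate's uninfected-control
#' nuclei, derives the percentile threshold, and calls every well on the
#' plate against it.
#'
#' @param measurements per-nucleus tibble with `plate`, `well`, `condition`,
#'   `median_gfp` (e.g. `simulate_experiment(...)$measurements`).
#' @inheritParams compute_threshold
#' @inheritParams call_and_index
#' @return a per-well tibble as in [call_and_index()], with the per-plate
#'   thresholds attached as attribute `"thresholds"` (named numeric vector).
#' @export
call_infections <- function(measurements, percentile = 99.9, min_nuclei = 50,
                            min_control_nuclei = 100) {
  stopifnot(is.data.frame(measurements),
            all(c("plate", "well", "condition", "median_gfp") %in% names(measurements)))
  plates <- unique(measurements$plate)
  thresholds <- vapply(plates, function(pl) {
    ctrl <- measurements$median_gfp[measurements$plate == pl &
                                      measurements$condition == "control"]
    compute_threshold(ctrl, percentile, min_control_nuclei)
  }, numeric(1))
  names(thresholds) <- plates
  out <- dplyr::bind_rows(lapply(plates, function(pl) {
    call_and_index(measurements[measurements$plate == pl, ],
                   thresholds[[pl]], min_nuclei)
  }))
  attr(out, "thresholds") <- thresholds
  out
}

#' Normalize infection indices to a reference line
#'
#' Divides each index by the reference-line index of the same timepoint, so
#' that plate-to-plate drift in overall infectability (virus batch, cell
#' density) cancels and only relative susceptibility remains.
#'
#' @param index numeric vector of infection indices.
#' @param reference_index matching reference indices (recycled if scalar).
#' @return `index / reference_index`.
#' @export
normalize_to_reference <- function(index, reference_index) {
  if (any(!is.finite(reference_index) | reference_index <= 0)) {
    stop("reference index missing or <= 0; cannot normalize this timepoint",
         call. = FALSE)
  }
  index / reference_index
}

#' Infection index stratified by nuclear area
#'
#' Splits nuclei into quantile bins of nuclear area and reports the infection
#' index per bin, plus the max - min spread across bins. Nuclear area tracks
#' cell-cycle stage (G2 nuclei are larger), so a flat profile indicates that
#' cell-cycle effects on infectability are minor.
#'
#' @param area numeric vector of nuclear areas (pixels).
#' @param infected logical vector of per-nucleus infected calls.
#' @param n_bins number of quantile bins (default 4).
#' @param min_nuclei minimum nuclei per bin on average (default 50); the
#'   input must contain at least `n_bins * min_nuclei` nuclei.
#' @return a tibble with `bin`, `area_lo`, `area_hi`, `n_nuclei`,
#'   `infection_index`; the spread is attached as attribute `"spread"`.
#' @export
stratify_by_area <- function(area, infected, n_bins = 4, min_nuclei = 50) {
  stopifnot(length(area) == length(infected), is.logical(infected))
  if (length(area) < n_bins * min_nuclei) {
    stop(sprintf("need at least %d nuclei for %d bins", n_bins * min_nuclei, n_bins),
         call. = FALSE)
  }
  breaks <- unique(stats::quantile(area, probs = seq(0, 1, length.out = n_bins + 1),
                                   type = 7, names = FALSE))
  if (length(breaks) < 2L) {
    warning("degenerate areas (all equal); returning a single bin")
    breaks <- c(breaks, breaks + 1)
  }
  bin <- cut(area, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  idx <- vapply(split(infected, bin), mean, numeric(1))
  n <- vapply(split(infected, bin), length, integer(1))
  out <- tibble::tibble(
    bin = seq_along(idx),
    area_lo = breaks[-length(breaks)],
    area_hi = breaks[-1],
    n_nuclei = as.integer(n),
    infection_index = unname(idx))
  attr(out, "spread") <- max(idx) - min(idx)
  out
}
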