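#' Summarize per-well infection indices into population summaries
#'
#' Collapses a per-well index table (one experiment and timepoint) to one row
#' per clonal population: replicate count, mean index and sample SD across
#' that population's technical replicate wells. QC-flagged wells and
#' control/reference wells are excluded.
#'
#' @param well_table per-well tibble from [call_and_index()] /
#'   [call_infections()] (or `simulate_well_indices()$wells`), with
#'   `population_id`, `infection_index` and optionally `condition`, `qc_flag`.
#' @param by grouping column(s); default `"population_id"`. Use
#'   `c("population_id", "branch")` to keep A/B branches apart, or add
#'   `"week"` for multi-timepoint tables.
#' @return a tibble with the grouping columns plus `n_replicates`,
#'   `mean_index`, `sd_index` (`NA` when a population has a single replicate).
#' @export
summarize_populations <- function(well_table, by = "population_id") {
  stopifnot(is.data.frame(well_table),
            all(c(by, "infection_index") %in% names(well_table)))
  x <- well_table
  if ("qc_flag" %in% names(x)) x <- x[!x$qc_flag, ]
  if ("condition" %in% names(x)) x <- x[x$condition == "infected", ]
  x |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(n_replicates = dplyr::n(),
                     mean_index = mean(.data$infection_index),
                     sd_index = stats::sd(.data$infection_index),
                     .groups = "drop")
}

#' Technical coefficient of variation
#'
#' The technical CV of one experiment is the average, over clonal
#' populations, of `sigma_i / mu_i`, where `sigma_i` is the sample SD
#' (denominator n - 1) of the infection indices of population `i`'s technical
#' replicate wells and `mu_i` their mean. It measures how much repeated wells
#' of the *same* population disagree.
#'
#' Populations with fewer than two replicates or with `mu_i = 0` carry no
#' technical information and are excluded with a warning.
#'
#' @param summaries population summary tibble from [summarize_populations()]
#'   (columns `n_replicates`, `mean_index`, `sd_index`).
#' @return the technical CV (scalar >= 0).
#' @export
technical_cv <- function(summaries) {
  stopifnot(is.data.frame(summaries),
            all(c("n_replicates", "mean_index", "sd_index") %in% names(summaries)))
  keep <- summaries$n_replicates >= 2 & summaries$mean_index > 0 &
    is.finite(summaries$sd_index)
  if (any(!keep)) {
    warning(sprintf("%d population(s) excluded from technical CV (single replicate or zero mean)",
                    sum(!keep)))
  }
  if (!any(keep)) {
    stop("no population with >= 2 technical replicates and positive mean index",
         call. = FALSE)
  }
  mean(summaries$sd_index[keep] / summaries$mean_index[keep])
}

#' Biological coefficient of variation
#'
#' The biological CV of one experiment is the sample SD (denominator n - 1)
#' of the per-population mean infection indices divided by their grand mean:
#' it measures how much *different* clonal populations disagree. An excess of
#' biological over technical CV is the fluctuation-test signature of a
#' heritable susceptibility state.
#'
#' @inheritParams technical_cv
#' @return the biological CV (scalar >= 0).
#' @export
biological_cv <- function(summaries) {
  stopifnot(is.data.frame(summaries), "mean_index" %in% names(summaries))
  mu <- summaries$mean_index[is.finite(summaries$mean_index)]
  if (length(mu) < 2L) {
    stop("biological CV needs >= 2 populations", call. = FALSE)
  }
  grand <- mean(mu)
  if (grand == 0) {
    stop("grand mean infection index is 0; biological CV undefined", call. = FALSE)
  }
  stats::sd(mu) / grand
}

#' Compare biological and technical noise across experiments
#'
#' Pairs each experiment's biological CV with its technical CV and tests the
#' differences with the two-sided Wilcoxon signed-rank test (exact null
#' distribution for small untied samples; zero differences are discarded,
#' matching the conventional "wilcox" zero handling).
#'
#' @param biological numeric vector of per-experiment biological CVs, or a
#'   data frame with columns `biological_cv` and `technical_cv`.
#' @param technical numeric vector of per-experiment technical CVs (omit when
#'   `biological` is a data frame).
#' @return an object of class `noise_result`: list with `pairs` (tibble of
#'   the paired CVs), `n_pairs`, `statistic` (signed-rank V), `p_value`,
#'   `mean_technical_cv`, `mean_biological_cv`.
#' @examples
#' compare_noise(c(0.31, 0.25, 0.22, 0.28, 0.24, 0.26),
#'               c(0.12, 0.10, 0.13, 0.09, 0.11, 0.12))
#' @export
compare_noise <- function(biological, technical = NULL) {
  if (is.data.frame(biological)) {
    stopifnot(all(c("biological_cv", "technical_cv") %in% names(biological)))
    technical <- biological$technical_cv
    biological <- biological$biological_cv
  }
  stopifnot(is.numeric(biological), is.numeric(technical),
            length(biological) == length(technical))
  ok <- is.finite(biological) & is.finite(technical)
  if (any(!ok)) {
    warning(sprintf("%d experiment(s) dropped pairwise (undefined CV)", sum(!ok)))
  }
  bio <- biological[ok]; tech <- technical[ok]
  n <- length(bio)
  if (n < 1L) stop("no experiment with both CVs defined", call. = FALSE)
  if (all(bio == tech)) {
    stop("all paired differences are zero; signed-rank test undefined", call. = FALSE)
  }
  if (n < 5L) {
    warning(sprintf("only %d pairs; the signed-rank test has very low power", n))
  }
  ht <- suppressWarnings(stats::wilcox.test(bio, tech, paired = TRUE,
                                            alternative = "two.sided"))
  structure(list(
    pairs = tibble::tibble(experiment = seq_len(n),
                           biological_cv = bio, technical_cv = tech),
    n_pairs = n,
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    mean_technical_cv = mean(tech),
    mean_biological_cv = mean(bio)),
    class = "noise_result")
}

#' @export
print.noise_result <- function(x, ...) {
  cat("<noise_result>\n")
  cat(sprintf("  %d experiments: mean biological CV %.3f vs mean technical CV %.3f\n",
              x$n_pairs, x$mean_biological_cv, x$mean_technical_cv))
  cat(sprintf("  Wilcoxon signed-rank V = %g, two-sided p = %.4g\n",
              x$statistic, x$p_value))
  invisible(x)
}

#' Per-experiment CV decomposition
#'
#' Runs [summarize_populations()], [technical_cv()] and [biological_cv()] on
#' one experiment's per-well index table.
#'
#' @inheritParams summarize_populations
#' @return one-row tibble with `n_populations`, `technical_cv`, `biological_cv`.
#' @export
decompose_noise <- function(well_table, by = "population_id") {
  s <- summarize_populations(well_table, by = by)
  tibble::tibble(n_populations = nrow(s),
                 technical_cv = technical_cv(s),
                 biological_cv = biological_cv(s))
}
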