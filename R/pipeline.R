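#' Simulate and analyse a set of fluctuation experiments
#'
#' Runs the full table-level pipeline end to end for several independent
#' experiments: simulate per-nucleus measurements, derive the per-plate
#' control threshold, call infections, summarize populations, and compute
#' each experiment's technical and biological CV. This is the synthetic
#' analogue of a multi-experiment fluctuation study.
#'
#' @param experiment_sizes integer vector: number of clonal populations in
#'   each experiment (one experiment per entry).
#' @param params a [sim_params()] object; its `seed` is combined with the
#'   experiment number so experiments are independent.
#' @param n_tech_replicates technical replicate wells per population.
#' @param percentile,min_nuclei passed to [call_infections()].
#' @return list with `per_experiment` (tibble: experiment, n_populations,
#'   technical_cv, biological_cv) and `test` (the [compare_noise()] result).
#' @export
run_noise_study <- function(experiment_sizes, params,
                            n_tech_replicates = 4,
                            percentile = 99.9, min_nuclei = 50) {
  stopifnot(length(experiment_sizes) >= 1)
  rows <- vector("list", length(experiment_sizes))
  for (e in seq_along(experiment_sizes)) {
    p_e <- params
    p_e$seed <- substream_seed(params$seed, "experiment", e)
    des <- sim_design(n_parental = 1,
                      n_subpop_per_parental = experiment_sizes[e],
                      n_tech_replicates = n_tech_replicates,
                      n_weeks = 1, include_ab_split = FALSE)
    ex <- simulate_experiment(p_e, des)
    wells <- call_infections(ex$measurements, percentile = percentile,
                             min_nuclei = min_nuclei)
    d <- decompose_noise(wells)
    rows[[e]] <- tibble::tibble(experiment = e, n_populations = d$n_populations,
                                technical_cv = d$technical_cv,
                                biological_cv = d$biological_cv)
  }
  per_experiment <- dplyr::bind_rows(rows)
  list(per_experiment = per_experiment,
       test = compare_noise(per_experiment))
}

#' Weekly correlation analysis of a replicate-split memory experiment
#'
#' For every week after the A/B split computes the three correlations of the
#' memory analysis — technical (replicate wells of the same culture),
#' biological (population means of branch A vs branch B) and the permutation
#' baseline — plus the reference-normalized temporal trend and the recovered
#' AR(1) persistence.
#'
#' @param wells per-well index table covering weeks and both branches
#'   (columns `population_id`, `branch`, `tech_rep`, `week`, `condition`,
#'   `infection_index`), e.g. `simulate_well_indices(...)$wells` or the
#'   output of [call_infections()] on a simulated memory experiment.
#' @param n_perm permutations for the baseline (default 1000).
#' @param seed seed for the permutation draws.
#' @param method correlation type for the technical/biological/permutation
#'   estimates (default Pearson).
#' @return list with
#'   * `by_week` — tibble: week, technical r + CI, biological r + CI,
#'     permutation mean and 2.5/97.5% band, ns;
#'   * `trend` — [temporal_trend()] output (reference-normalized);
#'   * `rho_hat` — [recover_persistence()] estimate using the mean technical
#'     correlation as the attenuation ceiling.
#' @export
memory_analysis <- function(wells, n_perm = 1000, seed = NULL,
                            method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(all(c("population_id", "branch", "week", "condition",
                  "infection_index") %in% names(wells)))
  inf <- wells[wells$condition == "infected", ]
  if ("qc_flag" %in% names(inf)) inf <- inf[!inf$qc_flag, ]
  weeks <- sort(unique(inf$week))
  weeks_post <- weeks[weeks >= 1]
  rows <- vector("list", length(weeks_post))
  for (i in seq_along(weeks_post)) {
    wk <- weeks_post[i]
    wk_tab <- inf[inf$week == wk, ]
    tech <- technical_correlation(wk_tab, method = method)
    s <- summarize_populations(wk_tab, by = c("population_id", "branch"))
    bio <- biological_correlation(s, method = method)
    wide <- split(s, s$branch)
    a <- wide$A$mean_index[order(wide$A$population_id)]
    b <- wide$B$mean_index[order(wide$B$population_id)]
    perm <- permutation_baseline(a, b, n_perm = n_perm,
                                 seed = if (is.null(seed)) NULL
                                        else substream_seed(seed, "perm", wk),
                                 method = method)
    rows[[i]] <- tibble::tibble(
      week = wk,
      technical_r = tech$r, technical_lo = tech$ci_lo, technical_hi = tech$ci_hi,
      n_technical_pairs = tech$n,
      biological_r = bio$r, biological_lo = bio$ci_lo, biological_hi = bio$ci_hi,
      n_populations = bio$n,
      permutation_mean_r = perm$mean_r,
      permutation_lo = perm$q025, permutation_hi = perm$q975)
  }
  by_week <- dplyr::bind_rows(rows)
  trend <- .reference_trend(wells)
  rho_hat <- tryCatch(
    recover_persistence(by_week$biological_r, by_week$week,
                        ceiling = mean(by_week$technical_r)),
    error = function(e) NA_real_)
  list(by_week = by_week, trend = trend, rho_hat = rho_hat)
}

# Reference-normalized per-culture indices -> weekly trend. Weeks without a
# positive reference index are omitted by normalize_to_reference()'s guard.
.reference_trend <- function(wells) {
  ref <- wells[wells$condition == "reference", ] |>
    dplyr::group_by(.data$week) |>
    dplyr::summarise(ref_index = mean(.data$infection_index), .groups = "drop")
  inf <- wells[wells$condition == "infected", ] |>
    dplyr::group_by(.data$population_id, .data$branch, .data$week) |>
    dplyr::summarise(mean_index = mean(.data$infection_index), .groups = "drop") |>
    dplyr::inner_join(ref, by = "week")
  bad <- !is.finite(inf$ref_index) | inf$ref_index <= 0
  if (any(bad)) {
    warning(sprintf("%d week(s) without usable reference omitted from the trend",
                    length(unique(inf$week[bad]))))
    inf <- inf[!bad, ]
  }
  inf$normalized_index <- normalize_to_reference(inf$mean_index, inf$ref_index)
  temporal_trend(inf[, c("week", "normalized_index")])
}
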