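#' Generator parameters for a synthetic fluctuation experiment
#'
#' Bundles every tunable of the hierarchical generator. The model has three
#' nested levels, all parameterized on the log-odds scale:
#'
#' * **population** — each clonal population carries a heritable latent
#'   susceptibility `theta` with stationary SD `sigma_pop` around
#'   `baseline_logodds`, evolving weekly with AR(1) persistence `rho`
#'   (or, with `dynamics = "two_state"`, switching between two discrete
#'   log-odds levels by a continuous-time Markov chain);
#' * **well** — every infected well perturbs `theta` by an independent
#'   technical draw with SD `sigma_tech` before the logistic link;
#' * **cell** — each of `cells_per_well` nuclei is infected with the well's
#'   probability, and its median reporter intensity is drawn log-normal from
#'   the infected (`fg_*`) or uninfected (`bg_*`) component.
#'
#' The defaults emulate the study conditions: a grand-mean infection index of
#' 50% (`baseline_logodds = 0`, the virus-titration working point), heritable
#' and technical noise levels that yield biological and technical CVs of
#' roughly 0.26 and 0.12, strong week-to-week persistence, and 5,000 cells
#' per well.
#'
#' @param baseline_logodds logit of the grand-mean infection probability.
#' @param sigma_pop SD (log-odds) of the heritable population component; >= 0.
#' @param sigma_tech SD (log-odds) of the well-level technical perturbation; >= 0.
#' @param rho weekly AR(1) persistence of the latent state, in \[0, 1\].
#' @param dynamics `"ar1"` (continuous latent log-odds) or `"two_state"`
#'   (discrete high/low susceptibility states).
#' @param switch_rates two non-negative rates per week, `c(high_to_low, low_to_high)`;
#'   used only by `"two_state"`.
#' @param state_logodds log-odds of the two states, `c(low, high)`;
#'   used only by `"two_state"`.
#' @param cells_per_well nuclei per well; >= 1.
#' @param bg_log_mean,bg_log_sd log-normal parameters of uninfected-nucleus
#'   median GFP intensity (arbitrary units).
#' @param fg_log_mean,fg_log_sd log-normal parameters of infected-nucleus
#'   intensity; `fg_log_mean` must exceed `bg_log_mean`.
#' @param area_mean,area_sd nuclear area distribution (pixels), normal
#'   truncated at > 0.
#' @param seed integer global seed; expanded into per-well substreams with
#'   [substream_seed()].
#' @return an object of class `sim_params` (a validated list).
#' @seealso [sim_design()], [simulate_experiment()]
#' @export
sim_params <- function(baseline_logodds = 0,
                       sigma_pop = 0.5,
                       sigma_tech = 0.2,
                       rho = 0.95,
                       dynamics = c("ar1", "two_state"),
                       switch_rates = c(high_to_low = 0.15, low_to_high = 0.15),
                       state_logodds = c(low = -1, high = 1),
                       cells_per_well = 5000,
                       bg_log_mean = log(100), bg_log_sd = 0.35,
                       fg_log_mean = log(1200), fg_log_sd = 0.5,
                       area_mean = 250, area_sd = 60,
                       seed = 1L) {
  dynamics <- match.arg(dynamics)
  for (nm in c("baseline_logodds", "sigma_pop", "sigma_tech", "rho",
               "cells_per_well", "bg_log_mean", "bg_log_sd", "fg_log_mean",
               "fg_log_sd", "area_mean", "area_sd", "seed")) {
    .assert_scalar_number(get(nm), nm)
  }
  if (sigma_pop < 0 || sigma_tech < 0 || bg_log_sd < 0 || fg_log_sd < 0) {
    stop("sigma_pop, sigma_tech, bg_log_sd and fg_log_sd must be >= 0", call. = FALSE)
  }
  if (rho < 0 || rho > 1) {
    stop("`rho` must lie in [0, 1]", call. = FALSE)
  }
  if (cells_per_well < 1) {
    stop("`cells_per_well` must be >= 1", call. = FALSE)
  }
  if (fg_log_mean <= bg_log_mean) {
    stop("`fg_log_mean` must exceed `bg_log_mean` (infected nuclei are brighter)",
         call. = FALSE)
  }
  if (area_mean <= 0 || area_sd <= 0) {
    stop("`area_mean` and `area_sd` must be positive", call. = FALSE)
  }
  if (dynamics == "two_state") {
    if (length(switch_rates) != 2L || any(!is.finite(switch_rates)) ||
        any(switch_rates < 0)) {
      stop("two_state dynamics require `switch_rates` = two non-negative rates per week",
           call. = FALSE)
    }
    if (length(state_logodds) != 2L || any(!is.finite(state_logodds))) {
      stop("two_state dynamics require `state_logodds` = two finite log-odds values",
           call. = FALSE)
    }
  }
  structure(
    list(baseline_logodds = baseline_logodds,
         sigma_pop = sigma_pop, sigma_tech = sigma_tech, rho = rho,
         dynamics = dynamics,
         switch_rates = c(high_to_low = unname(switch_rates[1]),
                          low_to_high = unname(switch_rates[2])),
         state_logodds = c(low = unname(min(state_logodds)),
                           high = unname(max(state_logodds))),
         cells_per_well = as.integer(cells_per_well),
         bg_log_mean = bg_log_mean, bg_log_sd = bg_log_sd,
         fg_log_mean = fg_log_mean, fg_log_sd = fg_log_sd,
         area_mean = area_mean, area_sd = area_sd,
         seed = as.integer(seed)),
    class = "sim_params")
}

#' Experimental design of a synthetic fluctuation experiment
#'
#' Describes the plate layout the generator emits: clonal populations
#' (subpopulations nested in parental populations), technical replicate wells,
#' weekly timepoints, the optional A/B biological split of the memory
#' experiment, and per-plate uninfected-control and reference-line wells.
#' Reference wells emulate the unexpanded starting line (the "A549" lane):
#' their latent state is pinned at `baseline_logodds`, with technical noise
#' only, and downstream indices are normalized against them.
#'
#' `n_weeks` counts weekly timepoints; they are labelled `0, ..., n_weeks - 1`
#' and each timepoint is one plate. Week 0 is the timepoint of the A/B split,
#' so both branches share their latent state there.
#'
#' @param n_parental number of parental clonal populations.
#' @param n_subpop_per_parental clonal subpopulations derived from each parental.
#' @param n_tech_replicates technical replicate wells per population and timepoint.
#' @param n_weeks number of weekly timepoints (>= 0; 0 emits nothing).
#' @param include_ab_split split every population into biological replicates
#'   A and B that are propagated independently after week 0.
#' @param n_control_wells uninfected-control wells per plate.
#' @param n_reference_wells reference-line wells per plate.
#' @return an object of class `sim_design`.
#' @export
sim_design <- function(n_parental = 1,
                       n_subpop_per_parental = 40,
                       n_tech_replicates = 4,
                       n_weeks = 1,
                       include_ab_split = FALSE,
                       n_control_wells = 4,
                       n_reference_wells = 2) {
  counts <- c(n_parental = n_parental,
              n_subpop_per_parental = n_subpop_per_parental,
              n_tech_replicates = n_tech_replicates,
              n_control_wells = n_control_wells,
              n_reference_wells = n_reference_wells)
  if (any(counts < 1) || any(counts != as.integer(counts))) {
    stop("all design counts except `n_weeks` must be integers >= 1", call. = FALSE)
  }
  if (n_weeks < 0 || n_weeks != as.integer(n_weeks)) {
    stop("`n_weeks` must be an integer >= 0", call. = FALSE)
  }
  structure(
    list(n_parental = as.integer(n_parental),
         n_subpop_per_parental = as.integer(n_subpop_per_parental),
         n_tech_replicates = as.integer(n_tech_replicates),
         n_weeks = as.integer(n_weeks),
         include_ab_split = isTRUE(include_ab_split),
         n_control_wells = as.integer(n_control_wells),
         n_reference_wells = as.integer(n_reference_wells)),
    class = "sim_design")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>\n")
  cat(sprintf("  dynamics: %s  baseline logit %.3g  sigma_pop %.3g  sigma_tech %.3g  rho %.3g\n",
              x$dynamics, x$baseline_logodds, x$sigma_pop, x$sigma_tech, x$rho))
  cat(sprintf("  cells/well: %d  bg ~ lognorm(%.3g, %.3g)  fg ~ lognorm(%.3g, %.3g)  seed %d\n",
              x$cells_per_well, x$bg_log_mean, x$bg_log_sd,
              x$fg_log_mean, x$fg_log_sd, x$seed))
  invisible(x)
}

#' @export
print.sim_design <- function(x, ...) {
  cat("<sim_design>\n")
  cat(sprintf("  %d parental x %d subpopulations, %d tech reps, %d weekly timepoints%s\n",
              x$n_parental, x$n_subpop_per_parental, x$n_tech_replicates,
              x$n_weeks, if (x$include_ab_split) ", A/B split" else ""))
  cat(sprintf("  per plate: %d control wells, %d reference wells\n",
              x$n_control_wells, x$n_reference_wells))
  invisible(x)
}

.population_ids <- function(design) {
  as.vector(t(outer(seq_len(design$n_parental),
                    seq_len(design$n_subpop_per_parental),
                    function(p, s) sprintf("P%02d.S%02d", p, s))))
}

.branches <- function(design) {
  if (design$include_ab_split) c("A", "B") else "none"
}
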