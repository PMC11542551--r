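#' Simulate one well of per-nucleus measurements
#'
#' Draws the nuclei of a single well. For an infected (or reference-line) well
#' the infection probability is `p = logistic(theta + N(0, sigma_tech^2))`;
#' for an uninfected control well `p = 0`. Each nucleus is infected with
#' probability `p`, its median reporter intensity is log-normal from the
#' infected (`fg`) or uninfected (`bg`) component of `params`, and its nuclear
#' area is normal truncated at zero.
#'
#' @param theta latent log-odds of the well's population.
#' @param params a [sim_params()] object.
#' @param condition `"infected"` or `"control"`.
#' @param seed optional integer; when given, the well is drawn from
#'   `set.seed(seed)` and is fully reproducible on its own.
#' @return a tibble with columns `nucleus_id`, `median_gfp`, `area_px`,
#'   `infected_truth`; the realized infection probability is attached as
#'   attribute `"p_well"`.
#' @export
simulate_well <- function(theta, params, condition = c("infected", "control"),
                          seed = NULL) {
  stopifnot(inherits(params, "sim_params"))
  condition <- match.arg(condition)
  if (!is.null(seed)) set.seed(seed)
  w <- .draw_well(theta, params, condition)
  out <- tibble::tibble(
    nucleus_id = seq_len(params$cells_per_well),
    median_gfp = w$gfp,
    area_px = w$area,
    infected_truth = w$infected)
  attr(out, "p_well") <- w$p
  out
}

# Low-level single-well draw; consumes the current RNG stream.
.draw_well <- function(theta, params, condition) {
  n <- params$cells_per_well
  p <- if (condition == "control") 0 else
    stats::plogis(theta + stats::rnorm(1, 0, params$sigma_tech))
  infected <- stats::runif(n) < p
  gfp <- numeric(n)
  n_inf <- sum(infected)
  if (n_inf > 0) {
    gfp[infected] <- stats::rlnorm(n_inf, params$fg_log_mean, params$fg_log_sd)
  }
  if (n_inf < n) {
    gfp[!infected] <- stats::rlnorm(n - n_inf, params$bg_log_mean, params$bg_log_sd)
  }
  area <- stats::rnorm(n, params$area_mean, params$area_sd)
  while (any(bad <- area <= 0)) {
    area[bad] <- stats::rnorm(sum(bad), params$area_mean, params$area_sd)
  }
  list(p = p, infected = infected, gfp = gfp, area = area)
}

#' Simulate a full synthetic fluctuation experiment
#'
#' Emits every well of the design — populations x technical replicates x
#' weekly timepoints x biological branches, plus per-plate uninfected-control
#' and reference-line wells — as a per-nucleus measurement table with well
#' metadata, together with the latent ground truth.
#'
#' Each timepoint is one plate. Every well is drawn from its own substream
#' derived from the global seed and the well's identity
#' ([substream_seed()]), so the same seed gives byte-identical output and
#' enlarging the design never changes the wells that were already present.
#' Reference-line wells use `theta = baseline_logodds` with technical noise
#' only; control wells have infection probability 0.
#'
#' @param params a [sim_params()] object.
#' @param design a [sim_design()] object.
#' @return an object of class `sim_experiment`: a list with
#'   * `measurements` — tibble, one row per nucleus, columns `nucleus_id`,
#'     `plate`, `well`, `population_id`, `parental_id`, `branch`, `tech_rep`,
#'     `week`, `condition`, `median_gfp`, `area_px`, `infected_truth`;
#'   * `latent` — the [simulate_latent()] ground-truth table;
#'   * `wells` — one row per well with its realized infection probability;
#'   * `params`, `design`.
#' @examples
#' ex <- simulate_experiment(sim_params(cells_per_well = 200, seed = 3),
#'                           sim_design(n_subpop_per_parental = 4))
#' @export
simulate_experiment <- function(params, design) {
  stopifnot(inherits(params, "sim_params"), inherits(design, "sim_design"))
  latent <- simulate_latent(params, design)
  wells <- .well_layout(params, design, latent)
  n_wells <- nrow(wells)
  if (n_wells == 0L) {
    return(structure(list(measurements = .empty_measurements(),
                          latent = latent, wells = wells,
                          params = params, design = design),
                     class = "sim_experiment"))
  }
  flags <- vector("list", n_wells)
  gfp <- vector("list", n_wells)
  area <- vector("list", n_wells)
  p_well <- numeric(n_wells)
  for (i in seq_len(n_wells)) {
    set.seed(substream_seed(params$seed, "well", wells$plate[i], wells$well[i]))
    w <- .draw_well(wells$theta[i], params, wells$sim_condition[i])
    flags[[i]] <- w$infected
    gfp[[i]] <- w$gfp
    area[[i]] <- w$area
    p_well[i] <- w$p
  }
  wells$p_well <- p_well
  n <- params$cells_per_well
  idx <- rep(seq_len(n_wells), each = n)
  measurements <- tibble::tibble(
    nucleus_id = rep(seq_len(n), times = n_wells),
    plate = wells$plate[idx],
    well = wells$well[idx],
    population_id = wells$population_id[idx],
    parental_id = wells$parental_id[idx],
    branch = wells$branch[idx],
    tech_rep = wells$tech_rep[idx],
    week = wells$week[idx],
    condition = wells$condition[idx],
    median_gfp = unlist(gfp, use.names = FALSE),
    area_px = unlist(area, use.names = FALSE),
    infected_truth = unlist(flags, use.names = FALSE))
  structure(list(measurements = measurements,
                 latent = latent,
                 wells = wells[setdiff(names(wells), "sim_condition")],
                 params = params, design = design),
            class = "sim_experiment")
}

.empty_measurements <- function() {
  tibble::tibble(nucleus_id = integer(), plate = character(), well = character(),
                 population_id = character(), parental_id = character(),
                 branch = character(), tech_rep = integer(), week = integer(),
                 condition = character(), median_gfp = numeric(),
                 area_px = numeric(), infected_truth = logical())
}

# One row per well of the design, with the latent theta attached.
# `condition` is the user-facing label; `sim_condition` collapses
# reference -> infected for the draw (reference wells are infected wells whose
# theta is pinned at baseline).
.well_layout <- function(params, design, latent) {
  weeks <- seq_len(design$n_weeks) - 1L
  pieces <- vector("list", design$n_weeks)
  for (wi in seq_along(weeks)) {
    wk <- weeks[wi]
    plate <- sprintf("plate_w%02d", wk)
    lat <- latent[latent$week == wk, ]
    inf <- lat[rep(seq_len(nrow(lat)), each = design$n_tech_replicates), ]
    inf$tech_rep <- rep(seq_len(design$n_tech_replicates), times = nrow(lat))
    infected <- tibble::tibble(
      plate = plate,
      well = sprintf("%s_%s_r%d", inf$population_id, inf$branch, inf$tech_rep),
      population_id = inf$population_id,
      parental_id = inf$parental_id,
      branch = inf$branch,
      tech_rep = inf$tech_rep,
      week = wk,
      condition = "infected",
      sim_condition = "infected",
      theta = inf$theta)
    control <- tibble::tibble(
      plate = plate,
      well = sprintf("CTRL_c%d", seq_len(design$n_control_wells)),
      population_id = "control", parental_id = "control", branch = "none",
      tech_rep = seq_len(design$n_control_wells),
      week = wk, condition = "control", sim_condition = "control",
      theta = -Inf)
    reference <- tibble::tibble(
      plate = plate,
      well = sprintf("REF_r%d", seq_len(design$n_reference_wells)),
      population_id = "reference", parental_id = "reference", branch = "none",
      tech_rep = seq_len(design$n_reference_wells),
      week = wk, condition = "reference", sim_condition = "infected",
      theta = params$baseline_logodds)
    pieces[[wi]] <- dplyr::bind_rows(infected, control, reference)
  }
  dplyr::bind_rows(pieces)
}

#' Simulate well-level infection indices directly
#'
#' A reduced generator for analyses that only need well-level infection
#' indices (the memory/correlation stage and large calibration sweeps): the
#' per-nucleus intensity layer is skipped and each well's index is drawn as
#' `Binomial(cells_per_well, p) / cells_per_well` with the same hierarchical
#' `p` as [simulate_experiment()]. Draws come from a single stream seeded by
#' the global seed.
#'
#' @inheritParams simulate_experiment
#' @return a list with `wells` (one row per well: metadata, `p_well`,
#'   `infection_index`, `n_nuclei`) and `latent` (ground truth).
#' @export
simulate_well_indices <- function(params, design) {
  stopifnot(inherits(params, "sim_params"), inherits(design, "sim_design"))
  latent <- simulate_latent(params, design)
  wells <- .well_layout(params, design, latent)
  set.seed(substream_seed(params$seed, "well-indices"))
  n_wells <- nrow(wells)
  eps <- stats::rnorm(n_wells, 0, params$sigma_tech)
  p <- ifelse(wells$sim_condition == "control", 0,
              stats::plogis(wells$theta + eps))
  k <- stats::rbinom(n_wells, params$cells_per_well, p)
  wells$p_well <- p
  wells$infection_index <- k / params$cells_per_well
  wells$n_nuclei <- params$cells_per_well
  list(wells = wells[setdiff(names(wells), "sim_condition")], latent = latent)
}

#' Simulate per-population plaque counts
#'
#' Emulates the late-infection readout: for each latent track row the plaque
#' count is drawn `Poisson(scale * logistic(theta))`, so plaque counts are a
#' noisy monotone readout of the same latent susceptibility that drives the
#' early infection index. Used to exercise the early-vs-late correlation
#' stage.
#'
#' @param tracks a latent-track tibble (rows define the populations scored;
#'   filter to one week/branch first if needed).
#' @param scale positive expected plaque count at infection probability 1.
#' @param seed optional integer seed.
#' @return `tracks` with a `plaque_count` column appended.
#' @export
simulate_plaque_counts <- function(tracks, scale = 50, seed = NULL) {
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) || scale <= 0) {
    stop("`scale` must be a single positive number", call. = FALSE)
  }
  stopifnot(is.data.frame(tracks), "theta" %in% names(tracks))
  if (!is.null(seed)) set.seed(seed)
  tracks$plaque_count <- stats::rpois(nrow(tracks), scale * stats::plogis(tracks$theta))
  tracks
}
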