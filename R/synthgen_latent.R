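#' Simulate latent susceptibility trajectories
#'
#' Draws one latent susceptibility track per clonal population and biological
#' branch over the weekly timepoints of `design`.
#'
#' With `dynamics = "ar1"` the latent log-odds follow a stationary AR(1):
#' `theta(0) ~ N(baseline, sigma_pop^2)` and
#' `theta(t+1) = baseline + rho * (theta(t) - baseline) +
#' sqrt(1 - rho^2) * sigma_pop * eta`, `eta ~ N(0, 1)`, so the cross-population
#' SD of `theta` equals `sigma_pop` at every week and the A/B branch
#' correlation at week `t` is `rho^(2t)` (both branches share `theta(0)` and
#' evolve independently afterwards).
#'
#' With `dynamics = "two_state"` each population switches between a low- and a
#' high-susceptibility state by a continuous-time two-state Markov chain with
#' the per-week `switch_rates`, sampled at weekly intervals from its
#' stationary distribution; `theta` takes the corresponding `state_logodds`
#' value.
#'
#' @param params a [sim_params()] object.
#' @param design a [sim_design()] object.
#' @return a tibble with columns `population_id`, `parental_id`, `branch`
#'   (`"none"`, `"A"` or `"B"`), `week`, `theta`, and `state`
#'   (`NA` for AR(1) dynamics).
#' @examples
#' tracks <- simulate_latent(sim_params(seed = 7), sim_design(n_weeks = 4))
#' @export
simulate_latent <- function(params, design) {
  stopifnot(inherits(params, "sim_params"), inherits(design, "sim_design"))
  pops <- .population_ids(design)
  branches <- .branches(design)
  if (design$n_weeks == 0L || length(pops) == 0L) {
    return(tibble::tibble(population_id = character(), parental_id = character(),
                          branch = character(), week = integer(),
                          theta = numeric(), state = character()))
  }
  weeks <- seq_len(design$n_weeks) - 1L
  out <- vector("list", length(pops) * length(branches))
  k <- 0L
  for (pop in pops) {
    init <- .latent_init(params, pop)
    for (br in branches) {
      k <- k + 1L
      traj <- .latent_branch(params, pop, br, init, design$n_weeks)
      out[[k]] <- tibble::tibble(
        population_id = pop,
        parental_id = sub("\\.S\\d+$", "", pop),
        branch = br,
        week = weeks,
        theta = traj$theta,
        state = traj$state)
    }
  }
  dplyr::bind_rows(out)
}

# Week-0 latent value, shared by the A and B branches of a population.
.latent_init <- function(params, pop) {
  set.seed(substream_seed(params$seed, "latent-init", pop))
  if (params$dynamics == "ar1") {
    list(theta = params$baseline_logodds + params$sigma_pop * stats::rnorm(1),
         state = NA_character_)
  } else {
    p_high <- .two_state_stationary(params$switch_rates)
    st <- if (stats::runif(1) < p_high) "high" else "low"
    list(theta = unname(params$state_logodds[st]), state = st)
  }
}

# Evolve one branch forward from the shared week-0 value. Each (population,
# branch) pair has its own substream, so A and B are independent given week 0.
.latent_branch <- function(params, pop, branch, init, n_weeks) {
  theta <- numeric(n_weeks)
  state <- rep(NA_character_, n_weeks)
  theta[1] <- init$theta
  state[1] <- init$state
  if (n_weeks == 1L) return(list(theta = theta, state = state))
  set.seed(substream_seed(params$seed, "latent-path", pop, branch))
  if (params$dynamics == "ar1") {
    innov_sd <- sqrt(1 - params$rho^2) * params$sigma_pop
    eta <- stats::rnorm(n_weeks - 1L)
    for (t in 2:n_weeks) {
      theta[t] <- params$baseline_logodds +
        params$rho * (theta[t - 1L] - params$baseline_logodds) +
        innov_sd * eta[t - 1L]
    }
  } else {
    u <- stats::runif(n_weeks - 1L)
    for (t in 2:n_weeks) {
      p_same <- .two_state_stay(params$switch_rates, state[t - 1L])
      state[t] <- if (u[t - 1L] < p_same) state[t - 1L] else
        setdiff(c("high", "low"), state[t - 1L])
      theta[t] <- unname(params$state_logodds[state[t]])
    }
  }
  list(theta = theta, state = state)
}

# Stationary P(high) of the two-state chain with rates (high->low, low->high).
.two_state_stationary <- function(rates) {
  a <- rates[["high_to_low"]]; b <- rates[["low_to_high"]]
  if (a + b == 0) 0.5 else b / (a + b)
}

# One-week self-transition probability of the two-state chain.
.two_state_stay <- function(rates, state) {
  a <- rates[["high_to_low"]]; b <- rates[["low_to_high"]]
  if (a + b == 0) return(1)
  decay <- exp(-(a + b))
  if (state == "high") b / (a + b) + a / (a + b) * decay
  else                 a / (a + b) + b / (a + b) * decay
}
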