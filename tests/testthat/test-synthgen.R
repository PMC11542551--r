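test_that("parameter and design validation rejects impossible inputs", {
  expect_error(sim_params(rho = 1.2), "rho")
  expect_error(sim_params(sigma_pop = -0.1), ">= 0")
  expect_error(sim_params(cells_per_well = 0), "cells_per_well")
  expect_error(sim_params(fg_log_mean = 1, bg_log_mean = 2), "exceed")
  expect_error(sim_params(dynamics = "two_state", switch_rates = c(-1, 1)),
               "switch_rates")
  expect_error(sim_design(n_tech_replicates = 0), "counts")
  expect_error(sim_design(n_weeks = -1), "n_weeks")
})

test_that("degenerate persistence rho = 1 freezes the latent state on both branches", {
  p <- sim_params(rho = 1, sigma_pop = 0.8, seed = 4)
  d <- sim_design(n_parental = 1, n_subpop_per_parental = 5, n_weeks = 6,
                  include_ab_split = TRUE)
  lat <- simulate_latent(p, d)
  for (pop in unique(lat$population_id)) {
    th <- lat$theta[lat$population_id == pop]
    expect_equal(th, rep(th[1], length(th)), tolerance = 1e-12)
  }
})

test_that("memoryless rho = 0 decorrelates the A/B branches after the split", {
  p <- sim_params(rho = 0, sigma_pop = 1, seed = 8)
  d <- sim_design(n_parental = 1, n_subpop_per_parental = 1500,
                  n_tech_replicates = 1, n_weeks = 3, include_ab_split = TRUE)
  lat <- simulate_latent(p, d)
  ab <- split_branches(lat, wk = 2)
  # 3 SE of a null correlation at n = 1500
  expect_lt(abs(cor(ab$a, ab$b)), 3 / sqrt(1500))
  # but the branches coincide at the split itself
  ab0 <- split_branches(lat, wk = 0)
  expect_equal(ab0$a, ab0$b)
})

test_that("AR(1) split correlation matches the closed form rho^(2t)", {
  p <- sim_params(rho = 0.9, sigma_pop = 1, seed = 11)
  d <- sim_design(n_parental = 1, n_subpop_per_parental = 2000,
                  n_tech_replicates = 1, n_weeks = 3, include_ab_split = TRUE)
  lat <- simulate_latent(p, d)
  ab <- split_branches(lat, wk = 2)
  r <- cor(ab$a, ab$b)
  se <- (1 - 0.6561^2) / sqrt(2000)
  expect_lt(abs(r - 0.9^4), 3 * se)
})

test_that("the AR(1) is stationary: cross-population SD equals sigma_pop at every week", {
  p <- sim_params(rho = 0.7, sigma_pop = 0.6, seed = 12)
  d <- sim_design(n_parental = 1, n_subpop_per_parental = 2000,
                  n_tech_replicates = 1, n_weeks = 5)
  lat <- simulate_latent(p, d)
  sds <- tapply(lat$theta, lat$week, sd)
  # SE of an SD estimate ~ sigma / sqrt(2 (n - 1))
  expect_true(all(abs(sds - 0.6) < 3 * 0.6 / sqrt(2 * 1999)))
})

test_that("two-state dynamics emit the configured state log-odds and respect zero rates", {
  p <- sim_params(dynamics = "two_state", switch_rates = c(0, 0),
                  state_logodds = c(-1.5, 1.5), seed = 5)
  d <- sim_design(n_parental = 1, n_subpop_per_parental = 50, n_weeks = 5)
  lat <- simulate_latent(p, d)
  expect_true(all(lat$state %in% c("high", "low")))
  expect_true(all(lat$theta %in% c(-1.5, 1.5)))
  # zero switch rates: every population keeps its initial state
  n_states <- tapply(lat$state, lat$population_id, function(s) length(unique(s)))
  expect_true(all(n_states == 1))

  p2 <- sim_params(dynamics = "two_state", switch_rates = c(2, 2), seed = 5)
  lat2 <- simulate_latent(p2, d)
  expect_gt(length(unique(tapply(lat2$state, lat2$population_id,
                                 function(s) paste(s, collapse = "")))), 1)
})

test_that("control wells draw every nucleus from the background distribution", {
  p <- quick_params(seed = 2)
  w <- simulate_well(0, p, condition = "control", seed = 10)
  expect_false(any(w$infected_truth))
  expect_identical(attr(w, "p_well"), 0)
  # background log-intensities have the configured location
  expect_lt(abs(mean(log(w$median_gfp)) - p$bg_log_mean),
            3 * p$bg_log_sd / sqrt(nrow(w)))
})

test_that("well-level infection counts follow the binomial oracle", {
  p <- sim_params(sigma_tech = 0, cells_per_well = 10000)
  w <- simulate_well(logit(0.2), p, seed = 42)
  expect_lt(abs(sum(w$infected_truth) - 2000), 3 * sqrt(10000 * 0.2 * 0.8))
  # logistic(0) = 0.5 working point
  w2 <- simulate_well(0, p, seed = 43)
  expect_lt(abs(mean(w2$infected_truth) - 0.5), 3 * sqrt(0.25 / 10000))
  expect_true(all(w$area_px > 0))
})

test_that("simulate_experiment emits exactly the designed wells", {
  p <- quick_params(seed = 1)
  d <- sim_design(n_parental = 1, n_subpop_per_parental = 2,
                  n_tech_replicates = 3, n_weeks = 1,
                  n_control_wells = 2, n_reference_wells = 2)
  ex <- simulate_experiment(p, d)
  expect_equal(nrow(ex$wells), 2 * 3 * 1 + 2 + 2)
  expect_equal(nrow(ex$measurements), nrow(ex$wells) * p$cells_per_well)
  expect_setequal(unique(ex$measurements$condition),
                  c("infected", "control", "reference"))
})

test_that("identical seeds give identical tables; different seeds differ", {
  p <- quick_params(seed = 17)
  d <- quick_design(n_pop = 3, n_rep = 2)
  ex1 <- simulate_experiment(p, d)
  ex2 <- simulate_experiment(p, d)
  expect_identical(ex1$measurements, ex2$measurements)
  expect_identical(ex1$latent, ex2$latent)
  p2 <- quick_params(seed = 18)
  expect_false(identical(simulate_experiment(p2, d)$measurements,
                         ex1$measurements))
})

test_that("enlarging the design does not perturb wells that were already present", {
  p <- quick_params(seed = 6)
  small <- simulate_experiment(p, quick_design(n_pop = 2, n_rep = 2))
  big <- simulate_experiment(p, quick_design(n_pop = 4, n_rep = 2))
  w <- "P01.S01_none_r1"
  expect_identical(small$measurements[small$measurements$well == w, ],
                   big$measurements[big$measurements$well == w, ])
})

test_that("with sigma_pop = 0 population means differ only by technical noise", {
  # Under the no-heritability null, each population mean of k replicate wells
  # has variance sigma_well^2 / k, so the biological CV (SD of means / grand
  # mean) sits a factor ~ 1/sqrt(k) below the technical CV (mean of per-
  # population SD / mean). Brute force over seeds confirms that ratio.
  k <- 4
  ratios <- vapply(1:20, function(s) {
    p <- sim_params(sigma_pop = 0, sigma_tech = 0.2, cells_per_well = 400,
                    seed = 100 + s)
    d <- sim_design(n_parental = 1, n_subpop_per_parental = 40,
                    n_tech_replicates = k, n_weeks = 1)
    wells <- simulate_well_indices(p, d)$wells
    s40 <- summarize_populations(wells)
    biological_cv(s40) / technical_cv(s40)
  }, numeric(1))
  se <- sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - 1 / sqrt(k)), 3 * se + 0.02)
})

test_that("plaque counts are a monotone noisy readout of latent susceptibility", {
  tracks <- tibble::tibble(population_id = sprintf("P%02d", 1:40),
                           theta = seq(-2, 2, length.out = 40))
  # vanishing relative noise at large scale: perfect rank agreement
  pc <- simulate_plaque_counts(tracks, scale = 1e5, seed = 1)
  expect_equal(cor(logistic(pc$theta), pc$plaque_count, method = "spearman"), 1)
  # no signal: counts are exchangeable Poisson noise
  flat <- tibble::tibble(population_id = tracks$population_id, theta = 0)
  fc <- simulate_plaque_counts(flat, scale = 50, seed = 2)
  noisy_early <- logistic(flat$theta) + rnorm(40, 0, 0.05)
  expect_lt(abs(cor(noisy_early, fc$plaque_count, method = "spearman")),
            3 / sqrt(40))
  expect_error(simulate_plaque_counts(tracks, scale = 0), "positive")
})

test_that("moderate-scale plaque counts reproduce the brute-force Spearman distribution", {
  # Independent oracle: 10,000-rep brute-force simulation of the same
  # generative model (theta ~ N(0, 0.8^2), counts ~ Poisson(50 * logistic))
  # gives the Monte-Carlo band of the early-vs-late Spearman r.
  set.seed(77)
  n_pop <- 40
  brute <- replicate(10000, {
    th <- rnorm(n_pop, 0, 0.8)
    cor(plogis(th), rpois(n_pop, 50 * plogis(th)), method = "spearman")
  })
  band <- quantile(brute, c(0.025, 0.975))
  p <- sim_params(sigma_pop = 0.8, rho = 1, seed = 31)
  d <- sim_design(n_parental = 1, n_subpop_per_parental = n_pop,
                  n_tech_replicates = 1, n_weeks = 1)
  lat <- simulate_latent(p, d)
  pc <- simulate_plaque_counts(lat, scale = 50, seed = 32)
  r <- cor(logistic(pc$theta), pc$plaque_count, method = "spearman")
  expect_gt(r, band[1])
  expect_lt(r, band[2])
})
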