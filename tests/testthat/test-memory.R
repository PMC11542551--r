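test_that("correlate reproduces hand-computed coefficients", {
  # Pearson: one swapped neighbour pair in a 4-point grid
  expect_equal(correlate(c(0.1, 0.2, 0.3, 0.4), c(0.1, 0.2, 0.4, 0.3))$r, 0.8)
  # Spearman: ranks (1..5) vs (2,1,4,3,5), sum d^2 = 4 -> 1 - 24/120 = 0.8
  expect_equal(correlate(1:5, c(2, 1, 4, 3, 5), method = "spearman")$r, 0.8)
  # and sum d^2 = 6 -> 1 - 36/120 = 0.7
  expect_equal(correlate(1:5, c(3, 1, 2, 4, 5), method = "spearman")$r, 0.7)
  expect_error(correlate(1:5, rep(1, 5)), "constant")
  expect_error(correlate(1:2, 2:1), "3 complete pairs")
})

test_that("identical replicates give a technical correlation of exactly 1", {
  idx <- runif(10, 0.2, 0.8)
  tab <- tibble::tibble(population_id = rep(sprintf("P%02d", 1:10), 2),
                        branch = "none",
                        tech_rep = rep(1:2, each = 10),
                        infection_index = rep(idx, 2))
  expect_equal(technical_correlation(tab)$r, 1)
})

test_that("technical correlation pools all unordered replicate pairs", {
  p <- sim_params(sigma_pop = 0.8, sigma_tech = 0.05, cells_per_well = 400,
                  seed = 23)
  d <- sim_design(n_parental = 1, n_subpop_per_parental = 18,
                  n_tech_replicates = 4, n_weeks = 1)
  wells <- simulate_well_indices(p, d)$wells
  tc <- technical_correlation(wells)
  expect_equal(tc$n, 18 * choose(4, 2))   # 108, the replicate-pair pooling
  expect_gt(tc$r, 0.9)                    # low technical noise -> near ceiling
  expect_true(tc$ci_lo <= tc$r && tc$r <= tc$ci_hi)
})

test_that("independent replicates from a no-heritability generator decorrelate", {
  p <- sim_params(sigma_pop = 0, sigma_tech = 0.3, cells_per_well = 400,
                  seed = 24)
  d <- sim_design(n_parental = 1, n_subpop_per_parental = 200,
                  n_tech_replicates = 4, n_weeks = 1)
  wells <- simulate_well_indices(p, d)$wells
  tc <- technical_correlation(wells)
  expect_lt(abs(tc$r), 3 / sqrt(tc$n))
})

test_that("biological correlation pairs branches by population id", {
  s <- tibble::tibble(population_id = rep(sprintf("P%02d", 1:8), 2),
                      branch = rep(c("A", "B"), each = 8),
                      mean_index = c(seq(0.2, 0.9, length.out = 8),
                                     seq(0.2, 0.9, length.out = 8)))
  expect_equal(biological_correlation(s)$r, 1)
  bad <- s[-3, ]
  expect_error(biological_correlation(bad), "unpaired population")
  expect_equal(biological_correlation(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.9))$n, 4L)
})

test_that("A/B correlation follows the attenuated AR(1) prediction", {
  # Analytic oracle: observed means = theta + N(0, s_obs^2) independently per
  # branch, so E[r] at week t is rho^(2t) * sigma_pop^2 / (sigma_pop^2 + s_obs^2).
  rho <- 0.9; s_pop <- 1; s_obs <- 0.4; wk <- 2; n <- 2000
  p <- sim_params(rho = rho, sigma_pop = s_pop, seed = 31)
  d <- sim_design(n_parental = 1, n_subpop_per_parental = n,
                  n_tech_replicates = 1, n_weeks = wk + 1,
                  include_ab_split = TRUE)
  ab <- split_branches(simulate_latent(p, d), wk)
  set.seed(99)
  obs_a <- ab$a + rnorm(n, 0, s_obs)
  obs_b <- ab$b + rnorm(n, 0, s_obs)
  r <- correlate(obs_a, obs_b)$r
  expected <- rho^(2 * wk) * s_pop^2 / (s_pop^2 + s_obs^2)
  se <- (1 - expected^2) / sqrt(n)
  expect_lt(abs(r - expected), 3 * se)
})

test_that("exhaustive permutation mean is exactly zero for any data", {
  # Independent oracle: under a uniform label permutation each pairing (i, j)
  # occurs (n-1)! times, so the centered cross-sum -- and with it the mean
  # permuted correlation -- cancels to exactly 0.
  x <- c(0.3, 0.1, 0.7, 0.4)
  y <- c(2.0, 1.1, 0.4, 3.2)
  pb <- permutation_baseline(x, y)
  expect_true(pb$exhaustive)
  expect_equal(pb$n_perm, factorial(4))
  expect_equal(pb$mean_r, 0, tolerance = 1e-12)
  # any non-degenerate data: same exact expectation
  pb2 <- permutation_baseline(c(5, 6, 9, 2), c(0.1, 0.5, 0.2, 0.9))
  expect_equal(pb2$mean_r, 0, tolerance = 1e-12)
})

test_that("random-mode permutation baseline is near zero and reproducible", {
  set.seed(8)
  x <- rnorm(60); y <- rnorm(60)
  p1 <- permutation_baseline(x, y, n_perm = 500, seed = 123)
  p2 <- permutation_baseline(x, y, n_perm = 500, seed = 123)
  expect_identical(p1$r, p2$r)
  expect_false(p1$exhaustive)
  expect_lt(abs(p1$mean_r), 0.02)
  expect_error(permutation_baseline(rep(1, 10), rnorm(10)), "constant")
  expect_error(permutation_baseline(1:3, 3:1), ">= 4")
})

test_that("early-vs-late correlation is Spearman with average-rank ties", {
  early <- c(0.2, 0.3, 0.4, 0.5, 0.6, 0.7)
  expect_equal(early_late_correlation(early, exp(early))$r, 1)
  expect_equal(early_late_correlation(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))$r, 0.8)
  expect_error(early_late_correlation(1:4, 1:4), ">= 5")
})

test_that("temporal trend is flat at 1 when populations equal the reference", {
  df <- tibble::tibble(week = rep(1:4, each = 10),
                       normalized_index = 1)
  tr <- temporal_trend(df)
  expect_equal(tr$mean_norm, rep(1, 4))
  expect_equal(tr$sd_norm, rep(0, 4))
  thin <- rbind(df, tibble::tibble(week = 5, normalized_index = 1.2))
  expect_warning(tr2 <- temporal_trend(thin), "omitted")
  expect_false(5 %in% tr2$week)
})

test_that("a baseline-only drift divides out under reference normalization", {
  # populations and reference share a common multiplicative drift by week
  drift <- c(1, 0.8, 1.3, 0.9)
  pop_level <- runif(10, 0.3, 0.7)
  df <- tibble::tibble(
    week = rep(1:4, each = 10),
    normalized_index = as.vector(outer(pop_level, drift)) /
      (0.5 * rep(drift, each = 10)))
  tr <- temporal_trend(df)
  expect_equal(diff(range(tr$mean_norm)), 0, tolerance = 1e-12)
})

test_that("persistence recovery is exact in the noiseless limit", {
  expect_equal(as.numeric(recover_persistence(c(0.9, 0.9, 0.9), 1:3,
                                              ceiling = 0.9)), 1)
  r <- 0.8^(2 * (1:5))
  expect_equal(as.numeric(recover_persistence(r, 1:5)), 0.8, tolerance = 1e-10)
  expect_error(recover_persistence(c(0.5), 1), ">= 2 weeks")
  expect_warning(expect_error(recover_persistence(c(-0.1, -0.2, 0.4), 1:3),
                              ">= 2 weeks"))
})

test_that("Fisher-z intervals cover the true correlation at the nominal rate", {
  set.seed(42)
  rho <- 0.5; n <- 50
  covered <- replicate(500, {
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    ci <- correlate(x, y)
    ci$ci_lo <= rho && rho <= ci$ci_hi
  })
  se <- sqrt(0.95 * 0.05 / 500)
  expect_lt(abs(mean(covered) - 0.95), 3 * se)
})

test_that("memory pipeline preserves the technical >= biological >= permutation ordering", {
  ok <- vapply(1:50, function(s) {
    p <- sim_params(rho = 0.9, sigma_pop = 0.6, sigma_tech = 0.1,
                    cells_per_well = 300, seed = 5000 + s)
    d <- sim_design(n_parental = 1, n_subpop_per_parental = 100,
                    n_tech_replicates = 4, n_weeks = 3,
                    include_ab_split = TRUE, n_control_wells = 1,
                    n_reference_wells = 1)
    wells <- simulate_well_indices(p, d)$wells
    ma <- memory_analysis(wells, n_perm = 50, seed = s)
    wk2 <- ma$by_week[ma$by_week$week == 2, ]
    wk2$technical_r >= wk2$biological_r &&
      wk2$biological_r >= wk2$permutation_mean_r
  }, logical(1))
  expect_true(all(ok))
})
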