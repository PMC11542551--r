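# Small parameter/design builders shared across test files.

quick_params <- function(...) {
  sim_params(cells_per_well = 300, ...)
}

# A one-plate design small enough for per-nucleus simulation in tests.
quick_design <- function(n_pop = 8, n_rep = 3, ...) {
  sim_design(n_parental = 1, n_subpop_per_parental = n_pop,
             n_tech_replicates = n_rep, n_weeks = 1,
             n_control_wells = 2, n_reference_wells = 1, ...)
}

# Latent A/B tables reshaped to paired per-week vectors.
split_branches <- function(latent, wk) {
  x <- latent[latent$week == wk, ]
  a <- x[x$branch == "A", ]
  b <- x[x$branch == "B", ]
  list(a = a$theta[order(a$population_id)],
       b = b$theta[order(b$population_id)])
}
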