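#!/usr/bin/env Rscript
# Simulate one synthetic fluctuation experiment at the study's design point
# (clonal subpopulations, technical replicate wells, uninfected controls and
# a reference lane at the 50% working point) and write the per-nucleus
# measurement table plus ground truth for the downstream steps.

suppressMessages(library(statefluct))

params <- sim_params(cells_per_well = 2000, seed = 101)
design <- sim_design(n_parental = 1, n_subpop_per_parental = 40,
                     n_tech_replicates = 4, n_weeks = 1,
                     n_control_wells = 4, n_reference_wells = 2)
message("simulating: ", design$n_subpop_per_parental, " subpopulations x ",
        design$n_tech_replicates, " replicate wells, ",
        params$cells_per_well, " cells/well")
ex <- simulate_experiment(params, design)
write_experiment(ex, "results/simulated_experiment")
message("wrote ", nrow(ex$measurements), " nuclei across ",
        nrow(ex$wells), " wells to results/simulated_experiment/")
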