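# statefluct

Fluctuation analysis of heritable infection susceptibility in clonal cell
populations.

When isogenic epithelial cells are exposed to a GFP-reporter adenovirus at a
dose titrated to a 50% infection index, some cells light up and some do not.
`statefluct` implements the Luria–Delbrück-style analysis that separates the
two candidate explanations — per-cell stochastic noise versus preexisting,
heritable cell states — for high-content microscopy readouts:

* **calling** — per-well infection indices from per-nucleus median GFP
  intensities, with the cutoff at the 99.9th percentile of the pooled
  uninfected-control nuclei of the same plate (Hyndman–Fan type-7
  interpolation, strict `>` at the cutoff), reference-line normalization and
  nuclear-area stratification;
* **noise** — per-experiment decomposition into
  technical CV = (1/n) Σᵢ σᵢ/μᵢ (variability across replicate wells of the
  same clonal population) and
  biological CV = SD(μ₁…μₙ)/mean(μᵢ) (variability across populations),
  compared across experiments with the exact two-sided Wilcoxon signed-rank
  test. Excess biological over technical CV is the fluctuation-test
  signature of a heritable susceptibility state;
* **memory** — for populations split into independently propagated branches
  A/B: weekly technical, biological (A vs B) and permutation-baseline
  correlations with Fisher-z intervals, reference-normalized temporal
  trends, and recovery of the persistence ρ of a stationary AR(1) latent
  state from the decay law corr(A,B at week t) = ρ²ᵗ;
* **synthgen** — a hierarchical generator (population log-odds → well
  technical noise → cell-level Bernoulli → log-normal intensities; AR(1) or
  two-state Markov weekly dynamics) emulating the study design, plus plaque
  counts as a late-infection readout;
* **imaging** — an optional fixture path that renders synthetic DAPI/GFP
  fields and re-extracts measurements (Otsu + connected components), so the
  tabular pipeline can be exercised from pixels.

## Worked example

The numbered drivers under `analysis/` run the whole workflow in order
(later steps read the tables earlier steps write under `results/`):

```sh
Rscript analysis/01_simulate.R          # synthetic experiment at the design point
Rscript analysis/02_infection_calling.R # thresholds and per-well indices
Rscript analysis/03_noise_decomposition.R
Rscript analysis/04_memory.R
Rscript analysis/05_early_late.R
```

`02_infection_calling.R` prints, for a 40-population experiment at 2,000
cells/well:

```
threshold(s): plate_w00 = 288.4 (a.u.)
reference lane infection index: 0.513 (working point ~ 0.5)
control wells called at 0.0010 (design rate 0.001)
infection index by area quartile: 0.513 0.514 0.513 0.512 (spread 0.002)
```

The control rate matches the 99.9th-percentile construction (0.001) and the
flat area profile shows nuclear size carrying no infection information in
the generator. `03_noise_decomposition.R` then reports, over six experiments
sized 40/14/18/40/39/40 populations:

```
  6 experiments: mean biological CV 0.248 vs mean technical CV 0.101
  Wilcoxon signed-rank V = 21, two-sided p = 0.03125
```

biological variability exceeding technical noise in every experiment —
p = 2/2⁶, the smallest two-sided value six pairs can produce — as expected
when a heritable component (`sigma_pop = 0.5`) is present. The memory driver
follows 18 populations split into A/B branches over nine weeks:

```
 week technical_r biological_r permutation_mean_r
    1       0.747        0.673          -0.000476
    4       0.834        0.523           0.007450
    9       0.879        0.292           0.013893
recovered rho = 0.950 (generator rho = 0.95)
```

The biological correlation stays far above the shuffled-label baseline
(≈ 0) for the whole course while decaying slowly toward it, and the decay
rate recovers the generator's persistence parameter.

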