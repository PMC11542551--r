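---
title: "Fluctuation analysis of heritable infection susceptibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fluctuation analysis of heritable infection susceptibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statefluct)
```

## The question and the experimental logic

Isogenic cells infected with the same dose of adenovirus split into infected
and uninfected fractions. Two explanations compete: per-cell stochasticity at
the moment of infection, or preexisting cell *states* that make some cells
durably more susceptible than others. The discriminating design is the
Luria–Delbrück fluctuation test transplanted to cell culture: grow many
clonal populations (each from a single cell), infect them in parallel with a
GFP reporter virus read out per nucleus, and compare the variability of the
per-population infection index *between* populations (biological) with the
variability *between replicate wells of the same population* (technical). If
susceptibility is purely stochastic at the cell level, clonal populations
are exchangeable and the two variabilities coincide; heritable states
inflate the between-population component. A second design — splitting
populations into two independently propagated branches A and B and
correlating them weekly — measures how long such states persist.

`statefluct` implements this analysis chain (infection-index calling, CV
decomposition, replicate-split correlation analysis) together with a
hierarchical generator that emulates the study design, so every statistical
property of the pipeline can be validated against known ground truth.

## The generative model

All susceptibility is modelled on the log-odds scale, where the components
add; the logistic link keeps well-level infection probabilities in (0, 1).
For population $i$, well $w$, week $t$:

$$
p_{iw}(t) = \mathrm{logistic}\!\left(\theta_i(t) + \varepsilon_w\right),
\qquad \varepsilon_w \sim \mathcal N(0, \sigma_\text{tech}^2),
$$

and each of the well's cells is infected independently with probability
$p_{iw}(t)$. The latent state follows a *stationary* AR(1):

$$
\theta_i(0) \sim \mathcal N(\mu, \sigma_\text{pop}^2), \qquad
\theta_i(t{+}1) = \mu + \rho\,(\theta_i(t) - \mu) +
\sqrt{1-\rho^2}\,\sigma_\text{pop}\,\eta_{it}.
$$

The $\sqrt{1-\rho^2}$ innovation scaling is deliberate: the cross-population
SD equals $\sigma_\text{pop}$ at *every* week, so observed week-to-week
stability of relative susceptibility maps onto $\rho \approx 1$ rather than
onto shrinking variance. After the week-0 split, branches A and B share
$\theta_i(0)$ and evolve independently, which gives the closed form

$$
\mathrm{corr}\!\left(\theta_A(t), \theta_B(t)\right) = \rho^{2t},
$$

the backbone of the memory analysis and of parameter recovery. As an
alternative state model, a continuous-time two-state Markov chain
(`dynamics = "two_state"`) switches between a low and a high log-odds level
with configurable per-week rates — the discrete "reversible switching"
picture. No quantitative switching rates are available for this system; the
defaults are placeholders chosen to exercise parameter recovery, not
biological estimates.

Reporter intensities are log-normal (microscopy intensities are
right-skewed), with separate background (uninfected) and foreground
(infected) components whose overlap is configurable so the threshold step
can be stressed. Nuclear areas are truncated-normal and independent of
infection, which is what makes the area-stratification null test meaningful.

### Default parameters and where they come from

| parameter | default | rationale |
|---|---|---|
| `baseline_logodds` | 0 | virus dose titrated to a 50% infection index, the assay's working point |
| `sigma_pop` | 0.5 | on the index scale (slope 1/4 at 50%) gives a biological CV ≈ 0.25, the observed scale of clonal variability |
| `sigma_tech` | 0.2 | gives a technical CV ≈ 0.10–0.12 at 50%, the observed replicate-well noise |
| `rho` | 0.95 | relative susceptibility is stable over at least 9 weeks, i.e. persistence near 1 |
| `cells_per_well` | 5000 | cells seeded per well in the assay format |
| `bg/fg_log_mean` | log 100 / log 1200 | an order-of-magnitude reporter separation with overlapping tails |

Each simulated well draws from its own RNG substream derived by hashing the
global seed with the well's identity, so a design can be enlarged without
perturbing wells that already existed, and identical seeds give
byte-identical tables.

## Infection-index calling

The cutoff is the 99.9th percentile of the pooled uninfected-control nuclei
of the same plate, computed with Hyndman–Fan type-7 interpolation (the
default of the mainstream numeric stacks, so thresholds are reproducible
across environments). Nuclei strictly above the cutoff are called infected;
ties count as uninfected — a conservative choice that is measure-zero for
continuous intensities. By construction the expected control false-positive
rate is 0.001, and the pipeline verifies this on its own controls. Pooling
scope is per plate: a plate is the natural unit of shared staining and
acquisition conditions. Wells with fewer than 50 nuclei (configurable) are
QC-flagged and excluded from downstream statistics; a well with no nuclei
has an undefined index, reported as missing rather than 0. Because calling
only uses the order of intensities relative to the cutoff, indices are
invariant under any strictly monotone transform applied jointly to
intensities and threshold — the property tests assert this.

## Noise decomposition

Per experiment, with $\mu_i$ and $\sigma_i$ the mean and SD of population
$i$'s technical-replicate indices:

$$
\text{technical CV} = \frac1n \sum_{i=1}^n \frac{\sigma_i}{\mu_i},
\qquad
\text{biological CV} = \frac{\operatorname{SD}(\mu_1, \dots, \mu_n)}
{\frac1n \sum_i \mu_i}.
$$

All SDs are sample SDs (denominator $n-1$); at 2–4 replicates the
convention matters, and the unbiased-variance choice is used consistently.
Experiments' paired (biological, technical) CVs are compared with the
two-sided Wilcoxon signed-rank test, exact for small untied samples, zero
differences discarded — the behaviour of the implementation the field
commonly uses. With fewer than five pairs the test still runs but a
low-power warning is emitted.

**A calibration caveat worth knowing.** Under the no-heritability null
($\sigma_\text{pop} = 0$) the population means entering the biological CV
are averages of $k$ technical replicates, so the biological CV concentrates
near $\text{technical CV}/\sqrt{k}$, *below* the technical CV. The paired
differences are then systematically negative rather than symmetric about
zero, and the signed-rank test is not a calibrated 5% test of "no heritable
state" — it is a one-directional comparison whose null behaviour depends on
$k$. The package documents and tests this property rather than hiding it;
the scientific conclusion (biological ≫ technical) is unaffected because the
observed effect points in the opposite direction and exceeds the $\sqrt k$
handicap several-fold.

## Memory analysis

Three correlations are computed per week, Pearson by default (Spearman by
flag; Spearman is fixed only for the early-vs-late comparison, where rank
correlation is the named statistic):

* **technical** — all unordered pairs of distinct replicate wells of the
  same culture, pooled across cultures (36 split cultures × C(3,2) = 108
  pairs in the study-sized design). This estimates the measurement-noise
  ceiling.
* **biological** — branch-A population means against branch-B means, paired
  by population.
* **permutation baseline** — one margin's labels shuffled; for $n \le 7$ all
  $n!$ permutations are enumerated, where the mean permuted correlation is
  *exactly* zero (each pairing $(i,j)$ occurs $(n-1)!$ times, so the
  centered cross-sums cancel). The often-quoted $-1/(n-1)$ is the
  within-permutation correlation of two draws without replacement, a
  different quantity; the baseline reported here matches the near-zero
  shuffled correlation the design expects.

Confidence intervals use the Fisher z-transform at 95%; its coverage is
property-tested against simulated bivariate data. The persistence parameter
is recovered from the weekly biological correlations via
$\log(r_t/\text{ceiling}) = 2t \log\rho$, least squares through the origin
with inverse-variance weights $\propto r^2/(1-r^2)^2$ (delta method on the
log scale). The weighting matters: at moderate $\rho$ the late-week
correlations decay into the noise floor, where $\log r$ is wildly unstable,
and an unweighted fit is dominated by exactly those weeks. The ceiling is
the mean technical correlation, which absorbs the attenuation that
measurement noise imposes on both estimates. Parameter recovery at 2,000
populations is within ±0.05 for $\rho$ of 0.7 and 0.95, which is the
validation surface of the latent model.

## Imaging fixture

The imaging module exists to exercise the tabular pipeline from pixels, not
to model microscopy: nuclei are non-overlapping disks (dart-throwing
placement with a retry cap), the GFP disk value is the record's median
intensity so medians survive rendering exactly, and segmentation is global
Otsu on DAPI plus connected components with a minimum-area filter.
On noiseless, well-separated fields this recovers counts, areas and medians
exactly — which is the fidelity target, no more. Saturation is clipped at
the 16-bit ceiling with a warning; fields round-trip losslessly through
multi-page TIFF.

## Problem sizes and determinism in the test suite

The packaged checks simulate at sizes chosen to make Monte-Carlo error small
relative to the asserted effect while keeping the suite quick: 2,000
populations for closed-form AR(1) checks and persistence recovery, 200
seeded runs for null calibration, 100 seeds for the power property, 50 seeds
for the correlation-ordering property (at 100 populations, where the
technical–biological gap is ≳4 SE), and Fig-2-sized experiments
(40/14/18/40/39/40 populations) at 1,000–2,000 cells per well for the
end-to-end fluctuation analysis. Every stochastic test fixes its seed;
statistical assertions use 3-SE bands derived from the quantity's sampling
distribution, not tuned constants.

## What the synthetic data does not capture

The generator emulates the *statistical* design: heritable population
states, well-level technical noise, binomial cell sampling, bimodal
intensities, reference and control lanes. It does not model spatial
population-context effects, plate-edge or illumination gradients,
segmentation errors on touching nuclei, cell-cycle coupling between area
and susceptibility, or virus-batch drift (the reference lane removes a
shared multiplicative drift by construction, and a dedicated test shows a
baseline-only drift divides out). Green tests therefore certify the
pipeline's statistical behaviour under the stated model, not the biology of
any particular dataset.
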