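---
title: "Quantifying local adaptation and soil-specific selection in reciprocal transplant experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying local adaptation and soil-specific selection in reciprocal transplant experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(localadapt)
```

## The experimental design and its estimands

`localadapt` analyses fully crossed site × soil × ecotype reciprocal
transplant experiments. Two locally adapted ecotypes (for example an Italian
and a Swedish *Arabidopsis thaliana* ecotype) are grown at both native sites,
each on soil collected from both sites, giving eight treatment cells. The
question the design answers is how much of the local ecotype's fitness
advantage is attributable to the soil rather than to the rest of the local
environment (climate above all): if soil type contributes to local
adaptation, selection against the non-local ecotype should be stronger on the
local soil than on the non-local soil at the same site.

Each planted seedling yields three observations:

* **survival to reproduction** (a binary flag; a plant that died before
  reproducing carries a fruit count of 0),
* **fruit number** of each reproductive plant, and
* **viable seeds per fruit**, counted from one intact mature fruit for the
  subset of reproductive plants that still had one at harvest.

From these the package computes four per-cell fitness components: mean
survival, mean fruits per reproductive plant (fecundity), mean seeds per
fruit over the measured plants, and the **overall-fitness proxy** — expected
seed number per planted seedling — defined as the per-plant product of fruit
number and the *cell mean* seeds per fruit, averaged over all planted
seedlings. Because dead plants carry zero fruits, the proxy factorizes
exactly:

$$
w_{\text{overall}} \;=\; \overline{\text{surv}} \times
\overline{\text{fruits}\mid\text{surv}} \times \overline{\text{seeds/fruit}},
$$

an identity `check_product_identity()` verifies to $10^{-12}$ relative
tolerance on every cell. Two conventions resolve the edge cases: an all-dead
cell has overall fitness 0 (every planted seedling produced zero seeds), even
though seeds per fruit is undefined there; a cell with survivors but no seed
measurement has overall fitness *missing* — the cell-mean multiplier is never
imputed from other cells, because the proxy multiplies by the
site–soil–ecotype mean specifically.

Selection against the non-local ecotype in a site–soil cell pair is

$$
s = 1 - \frac{w_{\text{non-local}}}{w_{\text{local}}},
$$

computed for each of the four components. $s$ is undefined when the local
mean is zero (including 0/0), equals 1 exactly when only the non-local mean
is zero, and is negative when the non-local ecotype is fitter. Soil-specific
adaptation at a site is summarized by
$\Delta s = s(\text{local soil}) - s(\text{non-local soil})$: positive values
mean selection is stronger on the site's own soil.

## Inference

**Confidence intervals** use a stratified nonparametric bootstrap: records
are resampled with replacement independently within each of the eight
site–soil–ecotype cells at the original cell sizes (default 1000 resamples),
and every statistic — including the seeds-per-fruit cell mean inside the
overall proxy — is recomputed on each resample. The proxy is part of the
estimator, so resampling must propagate through it; freezing the full-data
cell means would understate the interval width. Intervals are percentile
intervals with linear interpolation between order statistics
(`stats::quantile`, type 7), the minimal reading of a "bootstrap 95% CI";
bias-corrected variants are deliberately out of scope. Resamples on which $s$
is undefined (a resampled local-ecotype mean of zero — impossible at field
sample sizes, possible in toy data) are dropped and counted, and the interval
is flagged unreliable if more than 5% drop.

**The soil-contrast test** asks, per site, whether selection differs between
the two soils. Under the null hypothesis that soil type is irrelevant, soil
labels are exchangeable among the records of a site. Each permutation
replicate therefore shuffles the soil labels uniformly across all non-edge
records within the site — the individual plant record is the permutation
unit; its ecotype and all observations ride along, and per-soil totals are
preserved — and recomputes $\Delta s$ from scratch. Note that the ecotype
composition of each soil group varies across replicates (only in the
observed data is it exactly 256/264); this is the literal reading of
"permuting soil types within sites" and our simulations show the test holds
its nominal size under it.

The two-sided p value is formed by doubling a one-sided exceedance
proportion. Two conventions are offered:

* `tail = "signed"` (default): the proportion of permuted $\Delta s$ at least
  as extreme as the observed one *in its own direction* (non-strict), doubled
  and capped at 1. A doubled upper tail regardless of sign would exceed 1
  whenever the observed contrast is negative, so the direction-of-observed
  tail is the coherent reading of a doubled one-sided proportion.
* `tail = "absolute"`: the proportion of permuted $|\Delta s|$ at least the
  observed $|\Delta s|$.

Both are standard; they differ only when the permutation distribution is
asymmetric. By default the p value uses the add-one finite-sample correction
$p = \min\{1,\, 2(1+k)/(n_{\text{perm}}+1)\}$, which never returns 0; the
plain proportion is available (`plain_p = TRUE`) for strict replication of
analyses that used it. With `exhaustive = TRUE` the sampler is replaced by
complete enumeration of all distinguishable within-site soil assignments
(feasible for small sites) and the p value is the exact doubled tail over
the enumeration, which contains the observed assignment, so no add-one term
is needed. Replicates on which $\Delta s$ is undefined are dropped from
numerator and denominator and reported.

A single seed in `resampling_plan()` governs both resampling streams, so any
analysis is exactly reproducible given the seed and record order.

## The synthetic cohort generator

All testing and power analysis run on synthetic cohorts with known truth.
Per cell, the generator draws:

* survival ~ Bernoulli(`surv_prob`);
* fruits of survivors ~ negative binomial (mean `fruit_mean`, size
  `fruit_dispersion`) **conditioned on ≥ 1**, sampled exactly by inverse-CDF
  on $(P_0, 1]$. Overdispersion is the safe default for field fecundity
  data, and size → ∞ recovers the Poisson;
* a seeds-per-fruit count, present with probability `measure_prob`
  independent of plant size (missing completely at random — the simplest
  mechanism consistent with "had an intact mature fruit"; whether intactness
  correlates with plant size in the field is unknowable from scored data,
  and this assumption is the generator's, not a claim about any particular
  field data), drawn negative binomial with mean `seed_mean` and size
  `seed_dispersion`.

`derive_true_effects()` returns the closed-form truths this sampling model
implies: the fecundity truth is the *zero-truncated* mean
$\mu / (1 - (k/(k+\mu))^k)$, not the raw parameter, so analysis-side
estimates converge to the stated truth exactly; the seeds truth is the
measurement-model mean (subsampling assumed unbiased).

The default configuration is the package's reference study condition, chosen
once: cell sizes 256 (local) and 264 (non-local) per soil per site — 2080
plants in total; survival/fecundity/seed parameters giving strong adaptive
differentiation with an overall local:non-local fitness ratio of ≈ 4.4 at
site 1 (fecundity-dominated) and ≈ 6.1 at site 2 (survival-dominated),
matching the magnitudes reported for the Italian and Swedish *A. thaliana*
ecotype pair; and **no soil effect** — both soils share all parameters
within a site, so $\Delta s_{\text{true}} = 0$, the relevant reference point
for size and coverage simulations. Dispersions (fruits 1.5, seeds 8) and
`measure_prob = 0.7` are field-plausible round values: fruit counts in such
experiments are strongly overdispersed (variance several times the mean),
per-fruit seed counts much less so, and roughly two-thirds of reproductive
plants retain an intact fruit at harvest.

What the generator does **not** emulate: spatial structure (the design is
fully randomized; edge rows are excluded before analysis), block effects,
germination/dormancy dynamics, climate covariates, and any dependence of
seed measurement on plant size. Passing tests therefore validate the
estimator and test machinery under the stated sampling model, not the
field-specific error structure of any real dataset.

## Power analysis

`inject_soil_effect()` produces a configuration whose true overall-fitness
$\Delta s$ at a chosen site equals a target exactly, by rescaling the
non-local ecotype's seed mean on the non-local soil: overall expected
fitness is linear in the seed mean, so the factor
$(1 - s_l + \Delta s)/(1 - s_{nl})$ inverts the selection formula in closed
form while perturbing exactly one component. `run_power()` sweeps a grid of
injected effects and per-cell sample sizes, generating `n_sims` cohorts per
grid point and recording the rejection rate of the overall-fitness soil
contrast at the scenario site, its Monte Carlo standard error
$\sqrt{r(1-r)/n_{\text{sims}}}$, and the mean estimated contrast. Grid
points set all eight cells to the same size: the 256/264 asymmetry of the
field design is a precision tweak for fecundity estimates, not part of the
effect under study. Power sweeps default to reduced resampling (no
bootstrap, 200 permutations) as a fidelity/runtime trade-off — permutation p
values from 200 replicates are grainy but unbiased, which is what a
rejection-rate estimate needs.

At the reference design size (256/264 plants per cell) the sweep in the test
suite rejects a true overall-fitness contrast of $\Delta s = 0.2$ about 95%
of the time and one of $\Delta s \approx 0.08$–$0.1$ roughly half the time,
while holding its size at $\Delta s = 0$. This is why a null result at these
sample sizes is informative: contrasts of a few hundredths — the magnitudes
actually reported for this ecotype pair — are genuinely small effects, not
merely undetected large ones.

## Numerical and validation choices

* Simulation-based checks in the test suite use fixed seeds and sizes chosen
  to make Monte Carlo error negligible relative to the asserted tolerance:
  size and coverage are validated on 500 synthetic datasets at the full
  design size (500 permutations / bootstrap resamples each), parameter
  recovery at 5000 plants per cell, estimator consistency at 20 000 per
  cell, and exhaustive-enumeration agreement on sites of 8–12 plants.
* Cell means are unweighted arithmetic means; no shrinkage, trimming or
  imputation anywhere.
* Ties in the permutation distribution are handled by non-strict comparison
  (observed-equal counts as extreme), which keeps exhaustive p values
  strictly positive and sampled p values consistent with them.
* Degenerate inputs: zero-variance strata produce degenerate intervals equal
  to the point estimate; empty design cells are a hard configuration error
  at analysis time (never silently skipped); all-edge cohorts filter to an
  empty analysis set with a warning.
* Labels are free strings; the two-label universe is enforced at analysis
  time so the reader/writer stays generic.

## Known limitations

* The overall-fitness proxy ignores within-cell covariance between fruit
  number and seeds per fruit; with seed counts measured on one fruit per
  plant this is the best available estimator, but it is a proxy, not
  lifetime fitness.
* The percentile bootstrap can undercover slightly for strongly skewed
  component distributions at small cell sizes; coverage is validated at the
  reference design size only.
* The permutation test conditions on the observed per-soil totals; designs
  with severely unbalanced soils would make the signed convention's
  antisymmetry approximate rather than exact.
* No multiple-testing correction is applied across the eight site–component
  contrasts, matching standard practice for this design where the contrasts
  answer distinct questions.
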