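---
title: "Fitting probabilistic niche models to binary food webs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitting probabilistic niche models to binary food webs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichefit)
```

## The model

A binary food web on `S` species is an `S x S` connection matrix `A`,
where `A[i, j] = 1` means consumer `i` eats resource `j` (the diagonal —
cannibalism — is ordinary data). The classic one-dimensional niche
picture assigns each species a niche position `n` on a unit axis; each
consumer feeds on an interval of that axis of width `r` (the feeding
range) centred at a diet position `c`, usually below the consumer's own
position (hierarchical ordering). That deterministic interval rule
cannot be confronted with data through a likelihood: some observed links
get probability zero, and predictions jump discontinuously as parameters
cross interval edges.

The probabilistic version replaces the interval with a smooth unimodal
kernel. The probability that consumer `i` eats resource `j` is

```
P(i eats j) = a * exp( -((n_j - c_i) / (r_i / 2))^2 )
```

so the probability equals `a` when the resource sits exactly on the
consumer's feeding optimum and falls to `a/e` half a range away. Links
are independent Bernoulli draws, giving the log-likelihood

```
lnL = sum over all S^2 entries of  A_ij log P_ij + (1 - A_ij) log(1 - P_ij)
```

summed over every entry including the diagonal: an absent link is as
much data as a present one. Maximizing `lnL` over the per-species
`(n, c, r)` is *inverse* modelling: instead of assuming parameter
distributions and comparing simulated webs to data in aggregate, the data
assign each species its maximum-likelihood traits, which can then be
examined species by species.

### Conventions and their reasons

* **`a = 0.9999`, fixed.** The peak probability is held just below 1 for
  every species; a value of exactly 1 would send `log(1 - P)` to
  negative infinity whenever a predicted-certain link is absent. Earlier
  likelihood work found a freely fitted peak converges next to 1 anyway,
  so the parameter is spent nowhere.
* **`r` is a full width.** The kernel's `a/e` points sit at
  `c ± r/2`, which keeps `r` commensurate with the classic model's diet
  interval of width `r` centred at `c`. Any unimodal kernel could be
  substituted; only the Gaussian is implemented.
* **Floors.** Probabilities are clamped below at `p_floor = 1e-10` and
  ranges at `r_floor = 1e-6`, realizing the "range goes to zero"
  convention without `log(0)`. A floored non-link costs about `1e-10`
  nats, i.e. nothing.
* **Bounds.** `n, c` live in `[0, 1]`; `r` in `[r_floor, 2]`. The range
  cap fixes the scale gauge — on a unit axis, ranges beyond 2 are
  observationally indistinguishable.
* **Producers and specialists.** A species with no prey in the data has
  `c = 0` and `r = r_floor` imposed, which floors its whole row of link
  probabilities. A consumer of exactly one prey keeps `c` free but has
  `r` pinned at the floor: its likelihood is maximized when `c` lands
  exactly on the prey's niche position. These fixings are *not*
  subtracted from the nominal parameter counts used for AIC (the full
  model on 29 species counts `3 x 29 = 87`).
* **Gauge.** The likelihood is exactly invariant to reflecting the axis
  (`n -> 1 - n`, `c -> 1 - c`): fitted axes are identifiable only up to
  orientation. Reported full-model fits are re-oriented so niche
  position correlates non-negatively with prey count. Coupled variants
  are not re-oriented, since clamped linear couplings do not transform
  exactly under the reflection.

## The model family

Parameter redundancy (the fitted `n`, `c`, `r` are strongly mutually
correlated; a standardized PCA of the triples puts most variance on one
axis — see `pca_variance()`) motivates reduced variants in which some
per-species parameters become global functions of another:

| name | free per species | coupling | nominal k |
|---|---|---|---|
| `pnm` | n, c, r | — | 3S |
| `anm` | c, r | n from body mass | 2S |
| `r_of_c` | n, c | `r = r0 * exp(r1 * c)` | 2S + 2 |
| `r_of_n` | n, c | `r = r0 + r1 * n` | 2S + 2 |
| `c_of_n` | n, r | `c = c0 + c1 * n` | 2S + 2 |
| `c_and_r_of_n` | n | both linear in n | S + 4 |
| `random` | — | single uniform p | 1 |

The allometric variant (`anm`) pins each niche position to normalized
log body mass, `n_i = (log10 m_i - log10 m_min) / (log10 m_max - log10
m_min)`; the log scale is the natural choice because niche position
against mass follows a power law, and any log base gives the identical
normalized axis. The exponential range coupling uses the minimal
two-coefficient form `r0 * exp(r1 * c)`. Coupled values are clamped into
the model bounds rather than raising errors mid-optimization, which
keeps the annealer's state space a plain box. The `random` baseline has
the closed form `lnL = S^2 (C log C + (1 - C) log(1 - C))` at
`p = C = L/S^2` and is charged one parameter. Variants are compared by
`AIC = 2k - 2 lnL` with the nominal counts above.

## Estimation

The likelihood surface is high-dimensional (87 coordinates for a
29-species full model), multimodal, and contains needle-shaped optima:
a specialist's row is flat at the floor except within about `1e-6` of
its prey's position. Estimation therefore uses simulated annealing with
three deliberate additions:

1. **Single-coordinate proposals with incremental evaluation.** One
   uniformly chosen free coordinate is perturbed by a Gaussian step
   (scale `step_sigma = 0.1`) reflected at the bounds. A diet-position
   or range move touches one matrix row, a niche-position move one
   column, so each proposal costs `O(S)` rather than `O(S^2)`; the
   compiled kernel re-sums the full matrix at every stage boundary to
   cancel any accumulated rounding drift.
2. **Data-informed snap moves.** With probability `snap_prob = 0.1` a
   proposal instead sets a consumer's `c` exactly onto an observed
   prey's `n` (or an `n` onto an observed consumer's `c`), then faces
   the usual Metropolis test. Random walks cannot hit a `1e-6`-wide
   spike; snap moves make specialist optima (and tight generalist
   centres) reachable exactly.
3. **Deterministic polish.** After annealing, each coordinate is scanned
   over 33 grid points plus the snap candidates, with two shrinking
   local refinements, cycled twice. This is a cheap coordinate descent
   that finishes the stochastic search.

The schedule is geometric (`T0 = 1`, `cooling = 0.95`, 200 stages, 50
proposals per free parameter per stage) with Metropolis acceptance
`exp(delta lnL / T)` — none of these values is dictated by the model;
they are sized so an 87-parameter problem converges reliably in seconds.
Five restarts are run by default: the first warm-started from the web's
trophic ordering (damped prey-averaged trophic height sets the initial
`n` ranks; initial `c` is the mean prey position, initial `r` is 0.2),
the rest from uniform random states; ties between restarts go to the
lowest index so results are reproducible. Everything draws from R's RNG,
so a single `seed` fixes the outcome exactly.

`grid_search_oracle()` provides an independent check: an exhaustive
lattice maximization (capped at 10^7 points, so 2–3 species in
practice) evaluated by a separate vectorized code path. On such webs the
true optimum lies exactly on the lattice (specialist optima are lattice
points whenever `c` and `n` share a grid), and the annealer reproduces
it to full precision in the test suite.

## Goodness of fit

At the fitted parameters, `gof_report()` computes the expected number of
links `sum(P)`; the expected number of *observed* links predicted,
`N1 = sum of P_ij over observed links`, and its fraction `f_L = N1 / L`;
the expected fraction of all `S^2` matrix entries reproduced,
`sum(A P + (1 - A)(1 - P)) / S^2`; and per-species prey-side and
predator-side fractions `f_R`, `f_C` (undefined — reported `NA`, never
flagged — where a species has no prey or no predators). For the uniform
baseline these reduce to `f_L = C` and entries-correct
`C^2 + (1 - C)^2`, which at `C = 203/841` is 63.4%. `f_L` is only
meaningful when the expected link total is close to the observed total:
a model predicting every link present scores `f_L = 1` while being
maximally wrong about absences, which the entries-correct fraction
exposes.

## Post-fit diagnostics

`derived_ratios()` forms `x = r/n` and `c' = c/n` (undefined below
`n_eps = 1e-6`); `c' = 1` separates hierarchical diets (`c < n`) from
inverted ones. `distribution_tests()` checks the classic model's
distributional assumptions against the fitted values: `n` against
Uniform(0,1) and, after excluding any species with `c' > 1`, `c'`
against Uniform(0,1), both by one-sample Kolmogorov–Smirnov; and `r`
against an exponential whose scale is estimated by the sample mean, with
the asymptotic K-S p-value and no small-sample (Lilliefors) correction —
the uncorrected p is anti-conservative with an estimated scale, so it is
read qualitatively. `correlation_table()` computes Spearman rank
correlations for the ten canonical pairs among `n`, `c`, `r`, `x`, `c'`
and log body mass (the log is irrelevant to ranks; it is asserted so in
the tests), with Benjamini–Hochberg false-discovery-rate flags at
`alpha = 0.05`. When a constraint mask is supplied, producers are
dropped from all of these: their `c` and `r` are fixed by convention,
not estimated, and would contaminate the distributions.

## The synthetic generator

`generate_niche_web()` draws webs from the classic construction:
`n ~ U(0,1)`; relative range `x ~ Beta(1, 1/(2C) - 1)` so `E[x] = 2C`;
`r = x n`; `c ~ U(r/2, n)` (hierarchy, relaxed by half a range); a link
wherever `|n_j - c_i| <= r_i / 2`; the smallest-`n` species forced
basal. Diets are therefore *exactly* interval and expected connectance
is close to the target `C` (the forced-basal species costs a factor
`(S-1)/S`). `generate_pnm_web()` realizes independent Bernoulli draws
from any parameter set, giving ground truth for recovery studies.
`generate_body_masses()` lays log-linear masses over the axis,
`log10 m = intercept + slope * n + Normal(0, noise_sd)`, with defaults
(`-13`, `18`, `0.5`) spanning bacteria to large pelagic fish — the
magnitude range of a pelagic marine web.

What the generator does *not* emulate matters for interpreting green
tests: real webs have non-interval diets (taxonomic idiosyncrasies,
habitat structure), uneven taxonomic aggregation, and observation error
in both links and masses. Recovery of ground truth from simulated webs
shows the estimator works where the model is true; it cannot show the
model is true of any particular web.

## Problem sizes and tolerances in the tests

The suite exercises recovery at `S = 20`, target `C = 0.2`, 10 restarts
(the fitted lnL must dominate the true-parameter lnL and the true/fitted
niche orderings must agree to |Spearman| ≥ 0.9, orientation free);
oracle agreement on 2–3-species webs at lattice resolutions 0.02–0.05
(within `1e-2` nats); generator calibration over 200 webs at
`S = 29, C = 0.24` (mean connectance within ±0.02); and the uniform K-S
test's type-I error at the study's sample size `m = 29` over 2000 null
replicates (within Monte-Carlo error of 5%). These sizes were chosen as
the smallest at which each property is informative.

## Known limitations

* AIC uses nominal parameter counts; fixed producer/specialist
  parameters are deliberately not subtracted, so AIC differences between
  variants with different producer counts are slightly conservative.
* The annealer is a stochastic optimizer: the returned lnL is a lower
  bound on the true maximum. Restarts and the polish make S ≈ 30
  problems reliable in practice, but no certificate is produced.
* The exponential K-S p-value ignores scale estimation; the `c'` test
  conditions on the `c' > 1` exclusion.
* Only the Gaussian kernel and binary (unweighted) webs are supported.
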