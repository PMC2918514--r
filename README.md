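# nichefit

Maximum-likelihood fitting of one-dimensional niche models to binary
food webs.

A binary food web is an `S x S` connection matrix `A` with
`A[i, j] = 1` when consumer `i` eats resource `j`. The classic niche
model explains such webs by placing every species at a position `n` on a
one-dimensional niche axis and giving every consumer a feeding interval
of width `r` centred at a diet position `c`. `nichefit` implements the
*probabilistic* version of that model, in which the probability of a
feeding link is a Gaussian function of niche distance,

    P(i eats j) = a * exp( -((n_j - c_i) / (r_i / 2))^2 ),    a = 0.9999,

and the web is a set of independent Bernoulli observations with
log-likelihood

    lnL = sum_ij [ A_ij log P_ij + (1 - A_ij) log(1 - P_ij) ].

Because every link has non-zero probability and predictions vary
smoothly with the parameters, the model can be fitted by maximum
likelihood — species by species — instead of compared to data only
through simulated aggregates. The package provides:

* the likelihood kernel with producer/specialist constraints
  (`link_probability`, `probability_matrix`, `log_likelihood`);
* a simulated-annealing maximizer in compiled code with data-informed
  proposals, restarts and a deterministic polish (`fit`), plus an
  exhaustive `grid_search_oracle` for independent verification on tiny
  webs;
* the model family: the full model (`pnm`), the allometric niche model
  (`anm`, niche position = normalized log body mass), four
  reduced-parameter couplings, and the closed-form `random_model`
  baseline, compared by AIC with nominal parameter counts
  (`count_parameters`);
* goodness-of-fit statistics (`gof_report`, `flag_poorly_predicted`);
* post-fit diagnostics: parameter ratios, Kolmogorov–Smirnov
  distribution tests, Spearman correlations with body mass under
  Benjamini–Hochberg FDR control, PCA variance fractions
  (`derived_ratios`, `distribution_tests`, `correlation_table`,
  `pca_variance`);
* synthetic generators with known ground truth (`generate_niche_web`,
  `generate_pnm_web`, `generate_body_masses`) and plain-text I/O for
  webs and parameter sets;
* a command-line interface (`run_cli`; launcher in `inst/cli/`).

It is intended for ecologists studying food-web topology who want
species-level niche parameters, model comparison across niche-structured
variants, or ground-truth simulation studies of the inverse approach.

## Worked example

Simulate a 29-species web from known niche-model parameters, refit it,
and inspect the result:

```r
library(nichefit)

sw    <- generate_niche_web(S = 29, C = 0.24, seed = 1)   # ground truth
truth <- sw$true_params
web   <- generate_pnm_web(truth, seed = 2)$web            # Bernoulli realization
web   <- food_web(web$A, body_mass = generate_body_masses(truth$n, seed = 3))

web_stats(web)
#> S = 29, L = 179, C = 0.2128, L/S = 6.17, 3 basal, 5 specialists

f <- fit(web, "pnm", anneal_config(restarts = 5, seed = 4))
f
#> niche_fit: pnm, S = 29, lnL = -107.046, k = 87, AIC = 388.1 (restart 1)

round(random_model(29, 179)$aic, 1)
#> [1] 872.8

gof_report(probability_matrix(f$params, f$mask), web)
#> gof_report: expected links = 171.6, N1 = 136.9, f_L = 0.765, entries correct = 0.909

distribution_tests(f$params, mask = f$mask)
#> n ~ U(0,1):      D = 0.333, p = 0.00455
#> r ~ Exp(beta):   beta = 0.138, D = 0.192, p = 0.291
#> c' ~ U(0,1):     D = 0.363, p = 0.00144 (0 excluded with c' > 1)

cor(truth$n[!f$mask$producer], f$params$n[!f$mask$producer],
    method = "spearman")
#> [1] 0.9822222
```

Reading the output: the fitted model assigns the 179 observed links an
expected 76.5% probability mass (`f_L`) and reproduces 90.9% of all 841
matrix entries, against 21%/66% for the one-parameter random baseline —
an AIC gap of roughly 485. The recovered niche ordering matches the
generating ordering at Spearman 0.982 (the axis is identifiable only up
to reflection). `correlation_table(f$params, body_mass = web$body_mass,
mask = f$mask)` adds the ten rank correlations among parameters, derived
ratios and body mass with FDR flags.

The same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/nichefit.R simulate --S 29 --C 0.24 --seed 1 --out sim/
Rscript inst/cli/nichefit.R fit --web sim/web.csv --model pnm --seed 4 --out fit/
Rscript inst/cli/nichefit.R compare --web sim/web.csv --models random,c_and_r_of_n,pnm --out cmp/
```

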