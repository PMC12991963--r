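# exclodiv

Diversity trends and biotic homogenization in paired herbivore-exclosure
experiments.

`exclodiv` is for ecologists analysing long-term paired exclosure surveys
of plant (seedling/sapling) communities: each plot pair holds one fenced
*exclusion* plot, closed to medium-to-large terrestrial mammals, and one
open *control* plot, re-surveyed over many years. The package asks, at
every scale, the same question: **does the temporal trend of a diversity
metric differ between treatments?**

It provides, as composable tibble-in/tibble-out functions:

* **Alpha diversity** per plot and occasion — richness, Shannon
  (−Σ pᵢ ln pᵢ) and inverse Simpson (1/Σ pᵢ²) — computed after the
  Hellinger transformation x → √(x / Σx) of the community matrix.
* **Multiple-site beta diversity**: one abundance-based Bray–Curtis
  dissimilarity jointly over all plots of a treatment at one occasion,
  additively partitioned into *balanced variation* (the abundance analogue
  of species turnover) and *abundance gradients* (the analogue of
  nestedness):

  β_total = (Σmin + Σmax) / (2ΣA + Σmin + Σmax),
  β_bal = Σmin / (Σmin + ΣA), β_grad = β_total − β_bal,

  accumulating A (shared abundance) and min/max surplus over all plot
  pairs.
* **Jackknife uncertainty**: plot-level leave-one-out pseudo-values
  pᵢ = nθ − (n−1)θ₋ᵢ give standard errors and approximate 95% CIs for any
  multiple-site statistic.
* **Treatment-by-time models**: μᵢⱼ = β₀ + β₁·Time + β₂·Treatment +
  β₃·Time×Treatment (+ bᵢ) — a pair-level random intercept for plot-level
  alpha metrics (REML, `lme4`), ordinary least squares for treatment-level
  beta summaries. β₃, the treatment-by-time interaction, is the effect
  size throughout; component fits are gated on a significant total-beta
  interaction.
* **Cross-site contrasts**: pairwise z-tests on the β₃ estimates, with
  standard errors reconstructed from the reported CIs, rendered as forest
  plots.
* **A seeded survey generator** (`simulate_survey()`) emulating the
  experimental design (4 sites × 15 pairs, 18 occasions over 13 years,
  site-specific missing months, hyperdominant release, compositional
  convergence under exclusion) so every stage runs and is testable with no
  external data.

## Worked example

```r
library(exclodiv)

cfg    <- scenario_preset("homogenization", n_sites = 1, n_pairs = 15)
survey <- simulate_survey(cfg, seed = 2026)
survey
#> # A tibble: 15,144 × 7
#>    site  pair  plot  treatment month species count
#>    <chr> <chr> <chr> <chr>     <int> <chr>   <int>
#>  1 ITA   P01   P01C  control       0 sp001       8
#>  2 ITA   P01   P01C  control       0 sp004       2
#>  # ...

alpha <- alpha_table(survey)                 # one row per plot x occasion
beta  <- beta_summaries(survey)              # one row per occasion x treatment,
                                             # with jackknife SE/CI columns
fits  <- component_gating(fit_trend_models(survey, alpha = alpha, beta = beta))
dplyr::select(fits, site, family, metric, estimate_interaction,
              p_interaction, interpretable)
#> # A tibble: 6 × 6
#>   site  family metric      estimate_interaction p_interaction interpretable
#> 1 ITA   alpha  richness                0.0492   0.00000775    TRUE
#> 2 ITA   alpha  shannon                 0.000435 0.314         TRUE
#> 3 ITA   alpha  inv_simpson            -0.0102   0.220         TRUE
#> 4 ITA   beta   total                  -0.00165  0.0000000172  TRUE
#> 5 ITA   beta   balanced               -0.00175  0.00000000765 TRUE
#> 6 ITA   beta   gradient                0.000108 0.0289        TRUE
```

Reading the output: richness rises about 0.049 species/month *faster* in
exclusion plots than in controls (p ≈ 8×10⁻⁶), while total multiple-site
beta diversity declines ~0.0017/month relative to controls — the
exclosures are becoming compositionally more similar to each other.
Because the total-beta interaction is significant, the balanced-variation
and gradient components are flagged interpretable: here the decline is
carried almost entirely by balanced variation, i.e. by shifts in species
dominance rather than by uniform abundance differences. That joint
pattern — alpha up, beta down under exclusion — is the biotic
homogenization signature the homogenization scenario encodes.

Each fit is a broom-friendly object:

```r
tidy(fits$fit[[1]])     # coefficient table with Wald CIs
glance(fits$fit[[1]])   # one-row summary incl. sigma2_pairs, p_interaction
plot_alpha_trends(alpha, "richness")
plot_beta_trends(beta, "total")
```

With several sites, `pairwise_contrasts(fits, "richness")` compares the
interaction estimates across sites by z-test and `plot_contrasts()` draws
the forest plot. `run_pipeline(pipeline_config(...))` executes the whole
chain — validation, alpha, beta + jackknife, models, gating, contrasts —
and writes `alpha_diversity.csv`, `beta_diversity.csv`, `model_fits.csv`,
`residuals.csv`, `contrasts.csv` plus a seeded manifest; a thin CLI
wrapper with subcommands (`simulate`, `validate`, ..., `run-all`) lives in
`inst/scripts/exclodiv.R`.

See `vignette("exclodiv-methods")` for the models, the generator's
assumptions, and every numerical convention.

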