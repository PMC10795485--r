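# memfid

Mixture modeling and signal detection analysis of object-location memory
fidelity.

## What this is for

Lifespan studies of memory fidelity use continuous-report tasks: participants
study displays of three objects on an invisible circle, pick the studied
object over a similar lure (2AFC mnemonic discrimination), and reconstruct
its location on a dial. The signed angular error on a trial can come from
retrieved memory (of variable precision), from guessing, or from misbinding
another object's location. `memfid` is for researchers who need to separate
those sources and carry the result through a full subject- and group-level
analysis without hand-rolled glue code.

The core model is the von Mises–uniform mixture for errors
`e ∈ (−180, 180]`:

```
f(e) = pT · vM(e; 0, κ) + pNT · mean_j vM(e; δ_j, κ) + pU / 360
```

with retrieval success `pT`, precision `κ` (reported with its circular SD via
the standard `sd2k` mapping), optional swap components at the nontarget
offsets `δ_j`, and guess rate `pU = 1 − pT − pNT`. Fitting is by
multi-start maximum likelihood and by random-walk Metropolis MCMC under
diffuse priors (flat on the probability simplex and on SD ∈ [0.5°, 180°]),
with AIC/DIC model selection, split-R̂ diagnostics, posterior-overlap group
comparison, and quality flags for the exclusion rules such studies apply.

Around the model: differencing-model oddity and m-AFC d′ conversions
(`dprime_oddity3`, `dprime_mafc`) with below-chance recoding; a seeded
generative simulator of the task design (3-object displays ≥ 62.04° apart,
5-block sessions of 75 trials in STM and LTM formats); a tibble-first
pipeline (`compute_subject_metrics`, `build_composites`, `export_tidy`);
and the study-specific statistics (`bootstrap_correlation`, `steiger_z`,
`partial_correlation`, `within_display_dependency`).

## Worked example

Simulate a small two-group cohort through the short-term task, fit every
subject, and summarise by group:

```r
library(memfid)
library(dplyr)

ch <- simulate_cohort(n_per_group = c(young = 8, old = 8),
                      tasks = "STM", seed = 2024)
m <- compute_subject_metrics(ch$trials, seed = 1)
m |>
  group_by(age_group) |>
  summarise(mean_pT = mean(p_t), mean_kappa = mean(kappa),
            mean_mae = mean(mean_abs_error), mean_dprime = mean(d_prime))
#> # A tibble: 2 × 5
#>   age_group mean_pT mean_kappa mean_mae mean_dprime
#>   <chr>       <dbl>      <dbl>    <dbl>       <dbl>
#> 1 old         0.773       11.8     31.8       0.961
#> 2 young       0.909       16.0     19.9       1.34
```

Young simulated observers retrieve more often (`pT` 0.91 vs 0.77), more
precisely (`κ` 16.0 vs 11.8), make smaller raw errors (19.9° vs 31.8°), and
discriminate targets from lures better (d′ 1.34 vs 0.96) — the group
structure the generator was given.

A single subject's Bayesian fit, broom-style:

```r
f <- fit_mixture_bayes(ch$trials$signed_error_deg[ch$trials$subject_id == "s001"],
                       seed = 7)
tidy(f)
#> # A tibble: 5 × 6
#>   term   estimate    mean conf.low conf.high  rhat
#>   <chr>     <dbl>   <dbl>    <dbl>     <dbl> <dbl>
#> 1 p_t      0.939   0.916    0.805      0.987  1.00
#> 2 p_u      0.0613  0.0838   0.0125     0.195 NA
#> 3 p_nt     0       0        0          0     NA
#> 4 kappa    6.49    6.69     4.14      10.5   NA
#> 5 sd_deg  23.5    23.7     18.2       30.4    1.00
```

This subject retrieves on an estimated 94% of trials with a circular SD of
about 23.5° (κ ≈ 6.5); `autoplot(f)` overlays the fitted mixture on the
error histogram. Signal-detection conversions are one-liners:
`dprime_oddity3(0.875)` returns `3.755101`, the differencing-model
sensitivity for 87.5% correct odd-one-out performance, and
`derive_guess_cutoff(mixture_params(0.8, 10))` returns `49.03`, the absolute
error (degrees) beyond which guessing is the more likely source of a
response under that pooled fit.

## Package layout

- `R/angles.R` — circular primitives: error wrapping, von Mises density and
  sampler, SD↔κ conversion
- `R/mixture-fit.R`, `R/mixture-tools.R` — likelihoods, MLE/Bayesian fits,
  model selection, posterior overlap, quality flags, guess cutoff
- `R/psychophysics.R` — m-AFC and 3-stimulus-oddity d′, below-chance recoding
- `R/synthetic.R` — display/session/cohort simulation and group presets
- `R/pipeline.R` — subject metrics, composites, tidy export, CSV validation
- `R/stats-toolkit.R` — bootstrap r, Steiger's z, partial correlation,
  within-display dependency
- `vignettes/memory-fidelity-methods.Rmd` — models, assumptions, simulation
  design, limitations
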