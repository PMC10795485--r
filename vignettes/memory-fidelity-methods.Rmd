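---
title: "Models and methods for object-location memory fidelity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for object-location memory fidelity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memfid)
```

## The problem

In continuous-report object-location tasks, a participant studies a display of
three objects arranged on an invisible circle and later reconstructs the
location of a tested object by moving it around a response dial. The signed
angular error between target and response mixes qualitatively different
retrieval outcomes: trials where the location was retrieved (with variable
fidelity), trials where the participant guessed, and — potentially — trials
where the location of a *different* object from the same display was reported
(misbinding). A single summary such as the mean absolute error confounds these
sources: it cannot distinguish a participant who always remembers coarsely
from one who remembers precisely but only half the time.

`memfid` separates these processes with circular mixture models, converts
forced-choice and oddity accuracies to signal-detection sensitivities, and
supplies the surrounding machinery — a generative task simulator, a
subject-level pipeline with principled exclusions, and the bespoke statistics
(bootstrap effect sizes, dependent-correlation comparison, within-display
dependency) that this kind of study needs.

## The mixture model

Errors $e_i \in (-180, 180]$ degrees are modelled as draws from

$$f(e) = p_T \, \mathrm{vM}(e;\,0,\,\kappa) \;+\;
         p_{NT} \, \tfrac1m \sum_{j=1}^{m} \mathrm{vM}(e;\,\delta_j,\,\kappa)
         \;+\; p_U \, \tfrac{1}{360},$$

where $\mathrm{vM}$ is the von Mises ("circular Gaussian") density per degree,
$\delta_j$ are the signed offsets of the $m = 2$ nontargets from the target,
and $p_T + p_{NT} + p_U = 1$. Three nested candidates are supported:
uniform-only guessing, the standard two-component mixture ($p_{NT} = 0$), and
the swap mixture. $p_T$ is *retrieval success*, $\kappa$ is *precision*
(concentration of the remembered component; reported alongside its circular
SD, with the standard `sd2k` mapping $\bar R = I_1(\kappa)/I_0(\kappa)$,
$s = \sqrt{-2\ln\bar R}$, inverted by bracketed root search on
$\kappa \in [10^{-4}, 10^4]$). Swap components are averaged with equal weight
over the two nontargets.

### Fitting

*Maximum likelihood.* Proportions are optimized on the multinomial-logit
scale and $\kappa$ on the log scale inside $[0.5, 500]$, with 10 random
multi-starts (the first start is moment-based) and L-BFGS-B. On 20-trial
instances the result matches an exhaustive grid (steps of 0.01 in $p_T$,
0.25 in $\kappa$) to within $10^{-3}$ nats; the suite verifies this on 50
random instances.

*Bayesian.* Random-walk Metropolis on $(p_T[, p_{NT}], s)$ with flat priors
on the probability simplex and on the circular SD $s \in [0.5°, 180°]$; 3
chains with overdispersed starts, 1,000 burn-in and 5,000 retained draws per
chain by default. Convergence is summarised by split-$\widehat R$ per
parameter (threshold 1.05, configurable) and an autocorrelation-based
effective sample size; exceeding the threshold sets a `nonconvergence` flag
rather than raising an error, so cohort pipelines keep running. The point
estimate is the highest-posterior draw refined by bounded local optimization.
Because the priors are flat in $(p, s)$, this MAP coincides with the MLE in
that parameterisation — a property the test suite exploits as a cross-method
check ($|\Delta p_T| \le 0.05$, $|\Delta\kappa|/\kappa \le 10\%$ on 75-trial
data). Inside the sampler the SD-to-$\kappa$ map uses a precomputed monotone
spline (4,000 log-spaced knots); the exported `sd_to_kappa()` always uses the
exact root search.

*Model selection.* MLE fits are scored by AIC and Bayesian fits by DIC
(likelihood deviance, $2\bar D - D(\bar\theta)$); both appear in the ranking
table, and the Bayesian criterion decides when present. On 75-trial data
generated from the standard mixture the standard mixture wins essentially
always; on uniform data the guessing model is preferred in the clear majority
of replicates (the margin is only the 2-parameter penalty, so this preference
is strong but not certain).

### Fit quality and exclusions

Two phenomena make subject-level estimates untrustworthy: too few trials in
the von Mises component (low retrieval success inflates $\hat\kappa$), and
sampler nonconvergence. `flag_fit_quality()` flags fits with
$\hat p_T \times n < 10$ expected remembered trials (configurable), any
split-$\widehat R > 1.05$, or a parameter at its bound. The pipeline
propagates these into an `excluded` flag with a reason; excluded subjects are
retained in every export.

A caveat worth knowing: when the data are truly uniform, the MLE occasionally
keeps a nontrivial $\hat p_T$ with $\hat\kappa$ pinned at the lower bound —
a von Mises so broad it is practically uniform. The fitted *density* is still
close to guessing, and model selection prefers the uniform model, but
$\hat p_T$ alone should not be read as evidence of memory in that regime.

### Guess cutoff and adjusted precision

From a fit pooled across participants, `derive_guess_cutoff()` returns the
absolute error at which the weighted uniform density first exceeds the
weighted target density — beyond it, a response is more likely a guess. The
density-crossing rule is one defensible reading of a cutoff "derived from
modeling across all participants" and is kept as a free function so other
rules can be substituted. `adjusted_precision()` recomputes the circular SD
(and $\kappa$) from trials inside the cutoff only; at generative scale this
tracks the true $\kappa$ far better than the raw whole-sample dispersion,
which is contaminated by guesses.

### Group comparison by posterior overlap

`posterior_overlap()` computes the overlap coefficient
$100\int \min(f_A, f_B)$ of two kernel density estimates on a shared grid.
It is symmetric and bounded in $[0, 100]$; values near zero for pooled
group-level posteriors of $\kappa$ indicate credibly nonoverlapping groups.
Group-level fits pool trials across a group's subjects — a deliberate
simplification (no hierarchical shared-prior model; see Limitations).

## Signal detection conversions

Identification of the studied object against a similar lure is 2AFC;
perceptual discrimination is a 3-stimulus odd-one-out. `pc_mafc()` implements
$P_c = \int \phi(x - d')\,\Phi(x)^{m-1}dx$; `pc_oddity3()` implements the
differencing ("triangular") observer,
$P_c = 2\int_0^\infty \phi(x)\left[\Phi(-x\sqrt3 + d'\sqrt{2/3}) +
\Phi(-x\sqrt3 - d'\sqrt{2/3})\right]dx$, which equals exactly $1/3$ at
$d' = 0$ and lies below the 3AFC identification curve everywhere above
chance. Inverses are bracketed root searches on $d' \in [0, 10]$; round trips
hold to $10^{-4}$. The convention is anchored by the pair
$P_c = 21/24 = 0.875 \rightarrow d' = 3.76$.

The oddity inverse fails at or below chance, so below-chance observers must
be recoded. `recode_below_chance()` implements the published rule
$1 - 1/(2N)$ literally (default). That rule maps a below-chance score to a
near-perfect one, which is directionally surprising; because the intent
behind the printed formula is ambiguous, an alternative `rule = "chance"`
recodes to half a trial above chance instead (converted $d'$ just above 0).
We implement both rather than guess; the default follows the printed rule.

## The synthetic-data generator

The generator exists so that every stage is testable end to end without any
real dataset. It emulates the task design: three objects per display on an
invisible circle with pairwise separations of at least 62.04° (rejection
sampling, so placements are uniform over the feasible set); STM sessions of
5 blocks × 15 displays with one tested object each (75 trials); LTM sessions
of 5 blocks × 5 displays with all three objects tested, interleaved within
each block's test phase (75 trials). Responses follow the mixture above;
identification is Bernoulli at `pc_mafc(d', 2)`.

Group presets supply the generative parameters (e.g. young STM
$p_T = 0.89$, $\kappa = 18.12$; old LTM $p_T = 0.70$, $\kappa = 7.86$),
with optional between-subject heterogeneity as truncated-normal draws at the
preset SDs. Two coupling mechanisms, both off by default, create the
dependencies the statistics are meant to detect:

* **Item-location coupling** (`coupling`): the trial concentration is
  $\kappa\,e^{\pm c}$ on identification-correct/incorrect trials — a simple,
  monotone, recoverable form for the association between object-identity and
  location fidelity.
* **Display-level fidelity** (`display_coupling`): a standard-normal latent
  $g$ shared by a display's items scales $\kappa$ by $e^{cg}$ *and* shifts
  the retrieval-success logit by $cg$, so badly encoded displays produce more
  guessing and coarser recall for all their items. (A latent acting on
  $\kappa$ alone induces dependence too weak to matter once guessing noise is
  in the picture, which is why whole-display encoding failures are part of
  the mechanism.)

Seeding follows one root seed that spawns a substream per subject, so cohorts
are reproducible and individual subjects re-simulable.

What the generator does **not** emulate: perceptual similarity structure of
the stimuli, encoding-time or mask effects (carried as metadata only),
response time, sequential effects, and lapses that are not uniform guesses.
Passing recovery tests therefore show that the estimators are correct for
data obeying the assumed generative family — not that real data obey it.

## The statistics toolkit

* `bootstrap_correlation()`: percentile bootstrap (default 10,000 resamples)
  of Pearson's *r* after removing observations with $|z| > 3$ on either
  variable. Percentile rather than BCa, as the plain method is the stated
  procedure and its coverage at the sample sizes in play is adequate
  (verified by simulation in the suite).
* `steiger_z()`: Steiger's $Z_1^*$ for two dependent correlations sharing a
  variable, with the Dunn-Clark covariance at the pooled correlation; checked
  against an independently computed oracle value to $10^{-8}$.
* `partial_correlation()`: residual-residual correlation, for reading
  precision effects while controlling for retrieval success.
* `within_display_dependency()`: for LTM-format data, pairs each trial's
  absolute error with (a) the mean error of the other two items of its
  display and (b) an error sampled with replacement from all the subject's
  trials (the paper's baseline; with-replacement was chosen where the source
  is silent). The effect is the difference of subject-centered OLS slopes,
  with the random-baseline slope averaged over `n_draws` resamplings. This is
  deliberately not a mixed model: the predictor construction is the
  method-specific part, and the tidy export feeds external LMM software for
  exact replication.

## Simulation design of the validation suite

The suite's heavy checks run at the study's own scale, chosen once:

* Parameter recovery: 200 replicates × 75 trials for each of the six group ×
  task presets (median $|\Delta p_T| \le 0.05$,
  $|\Delta\kappa|/\kappa \le 20\%$); Bayesian 95% CI coverage at the
  representative preset $p_T = 0.8$, $\kappa = 12$ over 100 replicates
  (measured coverage ≈ 0.94–0.95).
* Group separation: full synthetic cohorts of 30/50/52 subjects with
  heterogeneity; pooled young-vs-old STM $\kappa$ posteriors overlap < 5%,
  and the young > middle > old $\kappa$ ordering reproduces across 100
  simulated experiments.
* Dependency: nulls from independent generation stay inside the permutation
  band; power is computed over 200 replicates of 12-subject LTM cohorts with
  `display_coupling = 1` (a strong holistic-encoding scenario) against the
  95th percentile of 200 matched independent-generation replicates.

## Numerical choices and degenerate inputs

Angles are degrees throughout; signed errors live in $(-180, 180]$ with
$+180$ at the antipode (a deterministic boundary convention). Von Mises
densities use exponentially scaled Bessel functions, so $\kappa$ up to
$10^4$ is safe. The uniform-only likelihood is evaluated in closed form
($n \ln(1/360)$), never optimized. Fits refuse fewer than 20 trials
(configurable); all-identical errors drive $\kappa$ to its bound and are
flagged rather than rejected. Proposals falling outside the prior support are
rejected by the sampler (valid Metropolis, at some cost in boundary mixing).
Ties in multi-start optimization break by first-found.

## Known limitations

Group-level fits pool trials rather than modelling subjects hierarchically;
with heterogeneous subjects the pooled $\kappa$ is a downward-shaded
compromise, which is acceptable for separation tests but not a substitute for
a hierarchical estimate. The swap model assumes the same $\kappa$ for target
and nontarget components. DIC is reported rather than WAIC/LOO. Mixed ANOVAs,
post hoc families and stepwise regressions are intentionally out of scope:
the pipeline exports tidy tables for the standard tools that own those
analyses.
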