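---
title: "Methods: prey-selection meta-analysis with preysel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prey-selection meta-analysis with preysel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(preysel)
```

## The model

A study contributes a diet table (occurrence counts of each prey species in
scats, stomachs, or DNA records) and an availability table (each species'
relative abundance in the local prey community). Selectivity is measured by
Jacobs' index

$$D = \frac{r - p}{r + p - 2 r p},$$

with $r$ the relative frequency of occurrence in the diet and $p$ the
availability. $D$ is antisymmetric in $(r, p)$, equals 0 exactly when use
matches availability, and saturates at $\pm 1$. Cross-study inference
treats study-level $D$ values for one species as replicate measurements: a
two-sided one-sample t-test against 0 classifies the species as preferred,
avoided, or neither. Linear modelling of selection uses Fisher's
transformation $z = \operatorname{atanh}(D)$, which removes the bounds.

Assumptions worth keeping in mind: occurrence counts are treated as
independent draws from the study's diet composition (no within-scat
correlation); availabilities are taken at face value from each study; and
studies are weighted equally (no inverse-variance weighting), so the test
asks whether selection is consistent across sites, not whether a pooled
effect differs from zero under a random-effects model.

## Estimators

**Traditional.** `selection_values()` computes per-study $r$, $p$, $D$, $z$;
`summarize_species()` pools by species. Two informative extremes are kept
by design: a species present in availability but absent from the diet has
$r = 0$ ($D = -1$), an observed avoidance; a species eaten but missing from
the availability table has $p = 0$ ($D = +1$) and is flagged (a config flag
drops these instead). t-tests run on raw $D$, not $z$: the printed
mean/SE/t columns of published summary tables reproduce on the raw scale,
and the bounded scale keeps the zero-variance sentinel interpretable.

**IPA.** Individual studies usually record only part of the prey
community. Ignoring the missing species biases the *other* species'
proportions, which are renormalized over the recorded subset. Iterative
preference averaging alternates (i) pooling per-species mean $z$ over all
studies and (ii) re-imputing, for each study, the species absent from both
of its tables: the missing species receives its cross-study mean
availability share and the diet share obtained by inverting Jacobs' index
at the current pooled estimate; the observed shares are rescaled to make
room and every $D$ in that study is recomputed on the completed simplexes.
Absence from the diet alone is data (an observed $r = 0$), never imputed.
The loop stops when the pooled estimates change by less than `tolerance`
(default 1e-8, cap 500 iterations). On complete data the loop is a no-op,
so the estimates equal the traditional per-species mean of $z$ after one
iteration; the estimator is invariant to study order and species labels.

Two numerical choices matter here:

* *Base-measure renormalization.* Reported availabilities are conditioned
  on each study's recorded subset, so their cross-study means are inflated
  when records are incomplete. The imputation base measure is therefore
  renormalized over the full community; without this the pooled estimates
  shrink visibly toward zero under heavy censoring.
* *Continuity correction for sampling zeros.* $\operatorname{atanh}$ maps
  $D = -1$ to the clamp boundary ($\approx -7.25$ at the default
  `eps = 1e-6`) regardless of sampling effort, and a single 0-of-$n$ count
  then dominates a z-scale mean. Inside the IPA, zero counts of available
  species receive half a record before normalization
  (`zero_correction = TRUE`), the classical continuity correction; the
  boundary value then reflects the study's sample size. The traditional
  estimator leaves $D = -1$ untouched by default.

**Biomass basis.** One large carcass yields many scats. The defecation
allometry $\log_{10}(\text{scats}) = a \log_{10}(\text{mass kg}) + b$
(defaults $a = 1.32$, $b = -0.89$, from 58 canid feeding trials; refit
from user data with `refit_allometry()`) converts occurrences to estimated
individuals consumed, $N_i = \text{occ}_i / 10^{a \log_{10} m_i + b}$,
whose proportions replace $r$. With equal masses the conversion cancels
exactly. `compare_methods()` contrasts estimators with a type-II
fixed-effects species-by-method ANOVA (the table is unbalanced, so
order-independent main-effect sums of squares are used) plus pairwise
Pearson correlations over aligned study-by-species values.

## Covariates and drivers

Body masses enter as $\frac{3}{4}$ of mean adult female mass, a standard
correction for the juveniles and subadults predators actually take
(`scale_body_mass()`; fixture tables whose masses are already scaled carry
a `mass_is_scaled` flag so the correction is never applied twice).
Rainfall is log10-transformed; rainfall and temperature are z-scored
(sample SD over non-missing entries); mass is log10 of the scaled value.
Group size (1 = solitary … 5 = very large groups) and threat (0 = none,
1 = injury, 2 = death) are modelled as continuous scores.

`fit_all_subsets()` enumerates every covariate subset (null model
included), fits Gaussian linear models by least squares, and ranks by AICc
by default — the small-sample form is the safer default at meta-analysis
sample sizes, and plain AIC is a flag. Weights are
$w_i \propto e^{-\Delta_i/2}$; a covariate's importance is the summed
weight of the models containing it; coefficients are full-model averaged
(zero substitution) with Burnham–Anderson unconditional standard errors.
Factor reference levels are fixed alphabetically for reproducible
coefficients; rows with missing values in the *selected* covariates are
dropped per model table, never imputed. The supported covariate list has
15 entries and is fully configurable, since the exact subset used in any
given synthesis is a judgement call. Partial correlations among numeric
covariates come from the inverse correlation matrix; with two covariates
this is the plain correlation, and an exactly collinear pair is an error,
not a silent drop.

Per-species geographic and density trends are simple regressions of $z$ on
latitude or predator density (`trend_regression()`); the seasonal analysis
is a type-II two-factor ANOVA of $D$ on period and species, interaction
included when the cell pattern allows it (raw $D$ by default, matching the
t-test convention; `response = "z"` switches).

## Prey weight ranges

`fit_segmented()` fits a continuous piecewise-linear model of selection on
$\log_{10}$ mass with $k$ estimated breakpoints: least squares on the hinge
basis $\{1, x, (x - b_j)_+\}$, with breakpoints relocated iteratively by
the standard linearization (regress on the hinge and its indicator, update
$b_j \leftarrow b_j + \gamma_j/\beta_j$, damped to keep the breakpoints
ordered and interior). If relocation fails to converge, a deterministic
coordinate-descent grid search refines the *initialization
neighbourhood* — deliberately local, because globally optimizing knot
locations inflates the spurious fit improvement on featureless data and
biases the breakpoint count upwards.

For breakpoint-count selection, AIC uses an effective parameter count of
**two** per estimated breakpoint ($2 + k + 2k + 1$ parameters for $k$
breakpoints). Estimated changepoints sit in a non-regular corner of
likelihood theory and a nominal 1-df count makes AIC anticonservative;
the 2-df effective cost follows the free-knot literature and restores the
intended null behaviour (straight-line data keeps $k = 0$ in well over 90%
of replicates in the test suite) without hurting recovery of genuine
breakpoints. `select_breakpoint_count()` also guarantees the residual sum
of squares is non-increasing in $k$ by always trying the previous fit's
breakpoints plus one extra knot.

The *preferred* prey weight range is operationalized explicitly (published
analyses rarely spell this out): a mass bin qualifies when its mean
selection exceeds the across-bin mean *and* its Tukey-adjusted contrast
with the lowest-mass bin is significant at $\alpha$; the preferred range is
the union of contiguous qualifying bins, and the *accessible* range is all
masses above that union's lower edge. Open outer edges are reported at the
observed mass extremes. Bins with fewer than two values are merged into
their neighbour before testing.

## The synthetic world

The generator gives every pipeline stage a ground truth. Preference acts
multiplicatively on availability: a study's expected diet proportions are
$r^*_i = w_i p_i / \sum_j w_j p_j$, so Jacobs' index has the closed form
$D^*_i = (w_i - S)/(w_i + S - 2 w_i p_i)$ with $S = \sum_j w_j p_j$, and
equal weights give $D^* = 0$ for every species — the natural null. Per
study, availability is Dirichlet around a community base measure
(concentration 30 by default: moderate between-study variation), counts
are multinomial, and censoring removes a species from *both* tables with
the stated probability, emulating studies that recorded only part of the
community. Defaults: 12 species, masses log-uniform on 0.01–357 kg (the
span of the packaged summary table), 200 dietary records per study (about
the per-dataset mean implied by the packaged synthesis: ~25,700 records
over 125 datasets), preference weights log-normal with `sdlog` 0.7
(typical $|D^*|$ up to ≈ 0.5), latitudes uniform on 19–55°.

What a green test does establish: the estimators are unbiased and
calibrated *under this world* — multinomial sampling, random censoring,
availability reported without error. What it does not: robustness to
non-random missingness (field studies omit species for ecological
reasons), availability measurement error, within-study overdispersion, or
spatial/temporal autocorrelation among studies. Those caveats apply
equally to the real analyses the package mirrors.

## Tunable parameters

| parameter | where | default | why |
|---|---|---|---|
| `alpha` | `summarize_species()` | 0.05 | two-sided preference test; no multiplicity correction by default (matching field practice), Holm via `adjust` |
| `eps` | `fisher_z()` | 1e-6 | clamp keeping $z(\pm 1)$ finite (≈ ±7.25) |
| `zero_correction` | `selection_values()` | off (on in IPA) | half-record continuity correction for 0-count available species |
| `tolerance`, `max_iterations` | `ipa_estimate()` | 1e-8, 500 | convergence of the pooled estimates |
| slope, intercept | `allometric_model()` | 1.32, −0.89 | printed canid feeding-trial allometry; refit supported |
| `criterion` | `fit_all_subsets()` | AICc | small-sample correction on by default |
| `min_avail_species`, `min_samples` | `prey_dataset()` | 3, 20 | the synthesis inclusion rules |
| `k_max` | `select_breakpoint_count()` | user | capped by the $n \ge 2(k+1)+k$ data requirement |

## Degenerate inputs and tie-breaks

$r = p = 0$ is undefined and the pair is dropped upstream. A species with
a single study gets no test (class `none`). Zero cross-study variance
yields a signed-infinity t sentinel with $p = 0$ (summary tables print
such rows; they are classified, not dropped). Near-significant results
($0.05 \le p < 0.10$) are annotated but classified `none`. Zero-variance
covariates, single-level factors, singular correlation matrices, and
collinear segmented predictors are errors naming the offending column.
Availability normalization is idempotent; CSV round trips are
bit-identical (`%.17g`).

## Known limitations

The IPA implementation follows the contract stated for it (reduction to
the traditional mean on complete data, permutation invariance, recovery of
the generator's closed-form truth under censoring); the originally cited
algorithm's unpublished details may differ in its imputation order or
weighting, so exact numerical agreement with any specific published IPA
run is not guaranteed. Mixed-effects pooling, spatial autocorrelation,
GAM-type smooth alternatives to segmented fits, and partial-carcass
consumption in the biomass conversion are deliberately out of scope.
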