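---
title: "Coupling a bioenergetic cow model to a breeding-scheme simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupling a bioenergetic cow model to a breeding-scheme simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(lactgain)
```

## The problem

Lactation efficiency in dairy cows — the share of ingested energy that ends
up in milk — is not a trait an animal "has"; it emerges from the daily
interplay between how much feed a cow can acquire and how she allocates the
resulting energy among maintenance, growth, gestation, milk and body
reserves. Conventional quantitative-genetic prediction of selection response
treats the derived traits (milk yield, intake, fertility, efficiency) as a
multivariate normal system with fixed (co)variances. That is adequate while
the energetic trade-offs that generated those covariances stay constant, but
it cannot anticipate what happens when selection shifts allocation
priorities, or when cows selected under generous feeding are moved to a
limiting environment.

`lactgain` implements the alternative: a mechanistic bioenergetic life-cycle
model whose only genetically variable inputs are four acquisition/allocation
(AA) traits, coupled to a stochastic breeding-scheme simulator through a
three-step loop:

1. simulate a baseline pedigreed population with the mechanistic model in
   both feeding environments and estimate genetic parameters linking the AA
   inputs to the derived traits (`simulate_herd()`,
   `derive_phenotypes()`, `estimate_variance_components()`);
2. predict the correlated selection response on the AA traits for a chosen
   total-merit index with a stochastic genomic breeding scheme
   (`run_scheme()`);
3. shift the AA means by the accumulated response, shrink their genetic
   variances for the Bulmer effect, and re-simulate the population under
   each environment; the change in the derived-trait means is the
   mechanistic prediction of selection response
   (`build_update()`, `predict_mm_response()`).

Because pregnancy, culling and feed restriction feed back on energy
allocation, the two prediction routes can disagree — most prominently on
fertility — and the package is designed to expose exactly those
disagreements (`compare_methods()`).

## The four genetic input traits

| trait | units | mean | meaning |
|---|---|---|---|
| `bas_acq` | kg DM/d | 7.00 | maximal intake of a mature non-lactating cow |
| `lact_acq` | kg DM/d | 10.25 | intake increase during lactation (peak increment) |
| `f_prio_gs` | 1/d | 0.0035 | decay rate of the growth allocation coefficient with age |
| `lact_all` | — | 0.56 | energy allocation to lactation at the start of lactation |

Founders carry true breeding values and phenotypes for these traits with
heritability 0.35 and phenotypic CV 0.10, no genetic or residual
correlations, in a paternal half-sib design (200 sires x 100 daughters at
full scale). Distributions are multivariate normal (the standard
infinitesimal-model assumption); draws outside biological support
(non-positive phenotypes, `lact_all` outside (0,1)) are resampled, which at
the default CV essentially never triggers.

## Feed environments

Two deterministic, 365-day-periodic calendars (`make_feed_calendar()`):

* **HS** (non-limiting): ad libitum offer (`Inf` sentinel), seasonal dietary
  ME content between 10.85 and 12.45 MJ/kg DM with annual mean 11.70;
* **MS** (limiting): the same ME trajectory plus a seasonal DM offer between
  10 and 16.8 kg DM/d with annual mean exactly 12.2.

Both curves use a raised-cosine-power shape
`min + range * ((1 + cos(2*pi*(d - peak)/365))/2)^p` with the exponent
solved by root finding so the 365-day mean is exact. A sum of two aligned
harmonics cannot satisfy the required min/max/mean triple for the offer
curve (the constraint system has no real solution: the mean sits much closer
to the minimum than to the maximum, which forces a peaked, non-sinusoidal
shape), hence this functional form. The phase (`peak_day`, default 61, about
two months after the start of the calving season) is a free calibration
knob; day 1 of the calendar is defined as the first day of the calving
season.

## The daily bioenergetic model

`simulate_herd()` advances every cow one day at a time from birth to
culling. Energy is accounted on the ME scale: `k_net` (default 1) converts
ME intake into the pool that is partitioned, and all energy-cost constants
(5.06 MJ per kg energy-corrected milk, 16 MJ per kg structural growth, 26 MJ
per kg labile reserves) are quoted on the same scale, so a single conversion
efficiency is absorbed into the cost constants rather than carried
separately.

Each day:

* **Intake.** Expected DMI = `bas_acq` times a saturating maturity curve,
  plus (when lactating) `lact_acq` times a normalized lactation curve with
  peak value exactly 1 at 56 days in milk. Achieved DMI is the minimum of
  expected DMI and the day's offer.
* **Maintenance first**, proportional to metabolic body weight
  (0.50 MJ/kg^0.75/d); a deficit is covered from reserves up to the daily
  mobilization cap.
* **Gestation next**: a fixed cubic trajectory of day of gestation (peak
  coefficient 0.14 at term, no individual variability) takes its share of
  the post-maintenance pool. Serving gestation before the lactation/growth
  split is what makes reproductive failure free energy for milk and
  reserves — the pregnancy-status feedback.
* **Lactation**: the allocation coefficient starts at `lact_all` at calving
  and decays at the fixed rate `rho_lact` (0.0012/d, no genetic variation in
  persistency). Milk *demand* is this coefficient applied to the energy the
  cow would acquire unconstrained, scaled by `drive_scale` (1.15) and driven
  by a milk-drive curve peaking at 28 days in milk — earlier than intake,
  which creates the early-lactation energy deficit. When the intake share
  falls short of demand the cow mobilizes reserves, but her willingness to
  do so declines logistically as the reserve ratio approaches
  `mob_reserves_half` (0.20): well-conditioned cows buffer milk against feed
  restriction, lean cows cut milk instead. This is the switch that makes
  milk yield, and not only reserves, respond to the MS restriction.
* **Growth**: coefficient `gamma_growth0` (0.9 at birth) decaying with age
  at the genetic rate `f_prio_gs` — the growth-to-survival allocation
  transfer. Structural mass only ever increases.
* **Reserves** take the residual. Labile mass saturates at
  `reserves_max_frac` (0.45) of structural mass; deposition beyond the
  ceiling is dissipated with maintenance (homeostatic control), which keeps
  the energy balance exact. The five allocations sum to the day's net energy
  to 1e-9 relative tolerance, asserted on every simulated day.

**Reproduction and culling.** Heifers are first mated at exactly 424 days of
age; cows are mated inside the 10-week seasonal window (opening on calendar
day 84, so that conceptions calve inside the calving season) after a 28-day
voluntary wait, with a 21-day oestrus cycle. Each insemination succeeds with
probability `p_milk * p_level * p_mob` — decreasing logistic in milk yield,
increasing in body-reserve ratio, decreasing in the day's mobilization.
Gestation lasts 282 days; dry-off at the earlier of 90 days before expected
calving and 56 days before the next calving season. Cows are culled when a
mating window closes without conception (at the end of the running
lactation; heifers immediately), when body reserves fall below 1% of body
mass, or after the eighth lactation.

**Calibration.** All constants above are free parameters of the reduced
form, fixed once so that the non-limiting baseline lands near the reference
behaviour: with the defaults, a 600-cow HS population completes about 6.2
lactations on average at 32% lifetime efficiency and 3,700 kg of
third-lactation 280-d ECM, and the same cows under MS complete about 4.1
lactations at 31% efficiency with lower intake, lighter third calvings and
longer conception intervals. The exact reference tables are not reproduced —
the original dynamic equations behind them are not part of this package's
sources — but every directional contrast (restriction lowers intake, milk,
body weight, fertility, longevity and lifetime efficiency; efficiency-only
selection collapses longevity) is, and those contrasts are what the test
suite pins.

**Common random numbers.** Conception uniforms are indexed per cow and
insemination event and drawn before the daily loop, so two runs with the
same seed but different calendars share their random stream. Paired
before/after populations in step 3 use the same device, which removes most
Monte-Carlo variance from the response estimates (an identity update yields
exactly zero response).

## Deriving the complex traits

`derive_phenotypes()` produces, per cow: body weight at first calving;
third-lactation 280-d cumulative ECM (lactations of 220–279 days are
completed with a cubic smoothing spline with 8 knots fitted to the observed
days, the spline's smoothing chosen by generalized cross-validation;
lactations under 220 days yield a missing value), mean third-lactation
intake, third-lactation efficiency, and the interval from first insemination
to conception; plus lifetime efficiency (total energy to milk over total ME
intake, birth to culling) and completed lactations. Third-lactation traits
exist only for survivors of two lactations — a selection bias that is the
point, not a bug; `lifetime_summary()` always averages over all simulated
cows.

## Quantitative-genetic layer

* `estimate_variance_components()`: method-of-moments sire-model ANOVA,
  exact for the balanced half-sib design. Heritability is four times the
  sire intraclass share; genetic covariances come from between-sire mean
  cross-products, residual covariances from the within-sire remainder.
  The information limit of 200 sire families puts a floor of about 0.07 on
  the sampling SD of a genetic correlation — recovery tests therefore
  average over replicate populations.
* `bend_correlation_matrix()`: iterated eigenvalue bending (floor negative
  eigenvalues, reconstruct, renormalize the diagonal) — idempotent, leaves
  positive-definite inputs untouched. The reference ten-trait genetic
  correlation matrix is already positive definite (smallest eigenvalue
  0.046), so bending it is a no-op.
* `tmi_trait_correlations()`: `cor(TMI, trait_i) = (Gw)_i / sqrt(w'Gw)` for
  index weights on the genetic-SD scale; checked against a 10^6-draw
  sampling oracle. Note the reference inputs are printed rounded to two
  decimals, which displaces a few of the reference index correlations by up
  to ~0.007.
* `bulmer_update()`: `h2' = alpha / (alpha + (1 - h2)/h2)` with residual
  variance unchanged; algebraically identical to scaling the additive
  variance by the retention factor `alpha`.
* `me_segments()` and `genomic_accuracy()`: the effective number of
  independent chromosome segments `2*Ne*L/ln(4*Ne*L)` (about 1973 at
  Ne = 350, L = 30 Morgans) and two switchable deterministic accuracy
  formulas built on it. Neither standard variant reproduces all four
  reference per-trait accuracies from the stated reference populations
  (the log-form recovers the fertility trait's 0.58 exactly but not milk's
  0.68), so the breeding-scheme simulator takes the reference accuracies
  (0.68/0.68/0.60/0.58) as configuration defaults rather than deriving
  them.

## The breeding scheme

`run_scheme()` simulates an overlapping-generation nucleus: females in
herds, mated to year-old genomically selected sires used for a single year;
calves preselected for genotyping on parent-average index; dams selected by
truncation on the index within herd among 1–5-year-olds; the top heifers
flushed twice in a MOET scheme with three offspring per mating, replacing an
equal number of natural matings; all matings random. True breeding values
are sampled on the full ten-trait panel (four AA traits, with basal
acquisition aliased to first-calving body weight and lactation allocation to
lactation efficiency, plus milk/intake/fertility in each environment) so
that limiting-environment trends arise as correlated responses. Genomic
information uses the pseudo-genomic device: each goal trait gets a
heritable pseudo-trait correlated with its TBV at the configured accuracy,
recorded with heritability 0.99 on genotyped animals.

Evaluation is animal-model BLUP via sparse Henderson mixed-model equations
(`blup_evaluate()`, pedigree inverse by Henderson's rules, solved with a
sparse Cholesky), run each year per goal trait as a bivariate model of the
trait and its genomic pseudo-trait on a sliding 7-year pedigree window. A
single 10-trait evaluation would carry slightly more cross-trait
information, but at the cost of an order of magnitude in runtime at the
yearly cadence; the bivariate route keeps the genomic information pathway
(which dominates candidate ranking here) intact, and `blup_evaluate()`
itself accepts arbitrary multi-trait models and is verified against a dense
generalized-least-squares oracle. One consequence worth knowing: goals that
lean on unrecorded traits (the efficiency-only goal) realize somewhat less
response than a full multi-trait evaluation would give them.

Outputs per goal: annual genetic gain per trait (regression of cohort-mean
TBV on birth year over the post-burn-in years, in genetic-SD units),
variance-retention factors for the AA traits (post-burn-in cohort variance
over the base variance), generation interval (mean parental age at birth of
offspring that themselves become parents), and the annual inbreeding rate
(exact Meuwissen–Luo coefficients on a per-cohort subsample).

The `"paper"` preset is the full-scale nucleus (20,000 cows, 200 herds, 100
sires, 4,000 genotyped per sex, 400 donors, 30 years, 30 replicates) and
takes hours; the `"desk"` preset (800 cows, 10 herds, 8 sires, 16 donors,
16 years, 3 replicates) runs in seconds per replicate and preserves the
goal ranking of milk responses, which is what the routine tests assert.
Presets change counts only, never model constants.

## Numerical and design choices

* Time step 1 day, explicit Euler updates of the two body masses.
* Energy conservation asserted every day at 1e-9 relative tolerance.
* Oestrus cycle 21 days; voluntary waiting period 28 days.
* `max_conceptions` is a counterfactual lever (block conception after n
  successes) used to demonstrate the pregnancy feedback in a controlled
  pair of otherwise identical runs; it is not part of the biology.
* Degenerate estimates are guarded: negative sire variances clamp to zero
  with a warning, correlations of zero-variance traits are set to zero, and
  heritabilities are floored at 0.005 when building residual variances for
  the mixed-model equations (the fertility trait's h2 of 0.01 is near that
  floor).
* The before/after populations of step 3 are fresh half-sib draws of 2,000
  cows by default (20 sires' worth of daughters each), paired by seed.
* Genetic correlations among AA traits are held at their initial values
  across horizons, and residual variances are never updated — only means
  and additive variances move.

## What the generator does and does not emulate

The synthetic system reproduces: seasonal pasture-type feeding with a
10-week mating season, half-sib population structure, genomic truncation
selection with realistic accuracies, the Bulmer loss of additive variance,
and the energetic trade-offs that couple milk, reserves, fertility and
longevity. It does not emulate: health traits, calf rearing detail, feed
composition beyond a single ME density, within-day dynamics, permanent
environmental effects on repeated records, mortality other than the three
culling rules, or real marker genotypes. Passing tests therefore certify
the internal consistency and the directional biology of the coupled system,
not numeric agreement with any particular commercial population.

## Known limitations

* The mechanistic map implies genetic correlations between AA inputs and
  derived traits that differ in magnitude from the reference panel (for
  example, lactation allocation correlates with milk more strongly here);
  consequently step-1 estimation should be rerun, rather than the reference
  panel reused, whenever the herd configuration changes.
* Response magnitudes at desk scale are smaller than full scale (lower
  selection intensity and more drift); rankings, signs and the
  mechanistic-versus-conventional contrasts are the stable quantities.
* The fertility trait's heritability (0.01) makes its conventional trend
  estimates noisy at desk scale; sign statements about it are made on
  replicate means.
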