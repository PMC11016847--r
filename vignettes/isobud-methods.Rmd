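---
title: "Methods: isotope-based bud dormancy analysis in isobud"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isotope-based bud dormancy analysis in isobud}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isobud)
```

`isobud` analyses twig-cutting assays of winter bud dormancy in temperate
deciduous trees. This vignette documents the models and procedures, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the numerical and design choices a maintainer should know about.

## 1. Isotope stage

### Background lines

Unlabelled ("natural abundance") bud water samples define, per species, a
linear relationship between the two water isotope deltas, fitted by ordinary
least squares of δ²H on δ¹⁸O (`fit_background_line()`). The assumption is
that evaporation and source-water changes move both isotopes along a stable
species-specific line even while the absolute values drift over winter, so
the line predicts the *expected* unlabelled δ²H of any sample from its
measured δ¹⁸O. At least 3 samples are required; zero variance in δ¹⁸O is a
degenerate-predictor error. Lines are pooled across sites by default
(`line_scope = "species"`); per-site fitting is available but halves the
sample size per line. Twig-tissue samples are scored against the same
species' bud line, as the two tissues' slopes are closely similar.

A fitted slope below 8 — the global meteoric water line — indicates
Rayleigh-type evaporative enrichment of the bud water (stronger accumulation
of ¹⁸O than ²H). `line_vs_gmwl()` reports the slope deficit and flags a line
as evaporative when slope + 2·SE < 8.

### Atom percent and label uptake

Delta values convert to heavy-isotope atom percent with the VSMOW reference
ratio (²H/¹H = 1.5576×10⁻⁴; ¹⁸O/¹⁶O = 2.0052×10⁻³; both overridable in
`isotope_constants()` — they are community reference values, not fitted
quantities). The conversion and its algebraic inverse are exact to
round-off; a property test verifies a relative round-trip error below
10⁻¹⁰ over δ ∈ [−900, 10000] ‰.

Short-term uptake of labelled water is the two-end-member mixing fraction on
the atom-percent scale, between the sample's predicted background and the
label water (δ²H = 2000 ‰ by default). Three numerical policies matter:

* **No clipping.** Measurement noise makes small negative uptake values
  inevitable when true uptake is near zero; clipping at 0 would bias
  campaign means upward near the winter floor. Values outside [−5, 105] %
  are flagged (`qc_flag`), never altered or dropped.
* **Ill-conditioned-label guard.** If the label exceeds the predicted
  background by less than `guard_permil` (default 100 ‰, ≈ 30× typical IRMS
  δ²H precision), the mixing denominator is dominated by noise and the
  computation errors out rather than returning junk.
* The background is predicted from each sample's *own* δ¹⁸O, so seasonal
  drift of the source water cancels by construction.

## 2. Phenology stage

Hourly logger series aggregate to daily mean/min/max/sd
(`aggregate_daily()`); days with fewer than 20 hourly readings are kept but
flagged, and no gaps are imputed. The same pass counts hours in the
chilling band ([0, 10] °C by default), which the dormancy-trajectory
generator consumes. First frost is the earliest day with minimum (or mean)
temperature below 0 °C; the pipeline restricts the dormancy-depth model to
campaigns at or after the earliest site's first frost, because thermal-time
patterns before dormancy induction are erratic.

Budburst outcomes per forced twig: success is the fraction of buds at stage
≥ 2 (budburst) of the 0–4 scale; thermal time is (stage-2 date − forcing
start) × (forcing − base temperature). With the default constant 20 °C
forcing and base 0 °C, thermal time is days × 20 °C·d; any other base only
rescales it monotonically under constant forcing, which is why 0 °C is an
innocuous convention. The stage-2 date is the first *monitoring* date at
which stage ≥ 2 was observed (twice-weekly checks) — no interpolation
between visits, which would invent precision. Twigs that never reach stage
2 are censored: they keep their success fraction but contribute no thermal
time, so the depth model has a smaller n than the success model. Same-day
budburst (0 days) is kept but flagged suspicious.

Water content is computed on a fresh-mass basis, 100·(fresh − dry)/fresh,
keeping values in [0, 100) and in the ~40–57 % range typical of winter buds;
a dry-mass basis is a config option.

## 3. Model stage

Four response models, all with donor tree as a random intercept (trees are
resampled every campaign, so campaigns within a tree are correlated):

| response | family / transform | date term | ANOVA |
|---|---|---|---|
| budburst success | binomial (per-twig counts), logit | continuous | type II |
| dormancy depth | Gaussian on ln(thermal time) | 2nd-order polynomial | type III |
| water content | Gaussian, percent scale | campaign factor (15 levels) | type III |
| uptake | Gaussian, percent scale | campaign factor (15 levels) | type III |

All models include species, site and every two-way interaction; for the
depth model both polynomial orders interact with species and site (the
interaction therefore carries 2×4 = 8 df against five species), and the
orthogonal polynomial keeps the two orders uncorrelated. Type III tests use
sum-to-zero contrasts, set on the factors at fit time. The log transform of
thermal time normalizes strongly right-skewed degree-day requirements;
percent-scale responses are modelled as Gaussian (a logit option exists for
water content). Campaign-as-factor models make no functional-form assumption
about the seasonal trajectories and allow campaign-level post-hoc
comparisons. Tukey HSD contrasts (via estimated marginal means) adjust
within one factor's family only; no across-model correction is applied, and
α = 0.05 throughout.

Mixed models are fitted with `glmmTMB`. If a mixed fit errors or fails to
converge (non-PD Hessian), the stage falls back to the corresponding
fixed-effects GLM/LM with cluster-robust standard errors by tree
(`sandwich::vcovCL`), recorded in the result's `note`; with fewer tree
clusters than coefficients the cluster-robust covariance is rank-deficient,
so the fallback degrades further to HC1 errors, and if a robust covariance
still cannot support the Wald hypotheses the ANOVA reverts to the
model-based covariance — each step is noted. A test verifies that on
well-conditioned data the fallback reproduces the mixed fit's coefficient
signs.

### Correlations

Species-specific Pearson correlations among the four proxies are computed on
(tree, campaign) means — twig- and bud-level values are averaged per tree
and campaign before pairing, since the two assays use different twigs of the
same tree and only join at that level (row-level pairing is a config
option). Campaigns 1–3 are excluded by default: leaves are still attached
and photosynthetically active then, and the senescence-time uptake peak
would otherwise dominate the uptake correlations. Entries with fewer than 4
complete pairs are reported as not-computable rather than dropped.

### Endodormancy onset

`detect_endodormancy_onset()` encodes the narrative "peak then collapse"
pattern as an explicit rule: the peak is the maximum campaign mean within
the autumn search window (all campaigns before 1 January in the pipeline);
the onset is the first later campaign whose mean falls below
`threshold_fraction` × peak (default 0.1) *and* stays below it at the next
campaign. The one-campaign persistence requirement rejects single noisy
dips; the relative threshold makes the rule invariant to uniform rescaling
of the series. If no campaign satisfies persistence (e.g. monotone series,
or a collapse only at the final campaign, where persistence cannot be
verified), the onset is reported absent and flagged rather than guessed.

## 4. What the synthetic generator emulates

`simulate_experiment()` generates a complete two-site, five-species
experiment: 5 trees per species and site, 12 main fortnightly campaigns
(October–April) plus 3 extra mid-winter campaigns (label and water content
only; the ninth campaign falls on 24 January), and 3 natural-abundance
campaigns the following winter.

* **Climate**: hourly series = seasonal sinusoid (coldest mid-January) +
  diurnal sinusoid + AR(1) noise. The default sites differ by 2.3 °C; over
  the October–April study window their daily-mean averages come out near
  6.4 and 4.1 °C with mean within-day SDs near 2.7 — a lowland/highland
  pair ~500 m apart in elevation.
* **Dormancy**: chilling hours accumulate in the [0, 10] °C band (a
  modelling choice — the chilling literature offers no single formula; both
  band and accounting are configurable). Log dormancy depth declines
  linearly with accumulated chilling from an autumn level
  (`initial_depth_dd`) towards the species' forcing requirement, and
  budburst success probability rises from `base_success` to `max_success`
  in proportion to that depth decline, which hard-wires the negative
  success–depth association every species should show. Species defaults
  span low-chill species able to burst all winter (beech-, oak-like),
  high-chill species with near-zero autumn success (maple-, lime-like) and
  a fast-release intermediate with an elevated uptake floor
  (hornbeam-like).
* **Uptake truth**: a Gaussian senescence bump (peak 40–70 %, late
  October–early November, width set by each species' senescence window)
  over a winter floor of 1.5–4 %, plus an optional pre-budburst rise for
  the two species programmed with one. Magnitudes are order-of-magnitude
  choices — no public axis calibration exists for this assay — and are
  documented as such.
* **Isotopes**: the latent uptake is imposed on the *atom-fraction* scale
  and inverted to a delta before instrument noise (1 ‰ δ²H, 0.2 ‰ δ¹⁸O) is
  added, so the pipeline's mixing arithmetic applied to noise-free data is
  *exactly* invertible — the airtight oracle behind the recovery tests.
  Natural-abundance δ¹⁸O drifts by up to +10 ‰ across the three background
  campaigns while staying on the species line, so the line fit stays valid
  by construction. Biological δ¹⁸O spread (SD 1.2 ‰) is kept separate from
  instrument noise and is never zeroed in "noise-free" runs, otherwise the
  background lines would be unidentifiable.
* **Water content**: autumn plateau, three-week post-senescence decline, a
  slow winter creep (up to 35 % of the spring gain — deacclimation), then
  the main rise starting `wc_rise_lead_days` (default 45 d, i.e. ~6–8
  weeks) before the species' natural budburst date.

What it does **not** emulate: frost damage, ABA/callose mechanisms, bud
micro-compartments, extraction-efficiency losses of the distillation
apparatus, missing data and sample losses of real campaigns, or
between-year climate variability. Passing recovery tests therefore show the
*pipeline* is correct and well-calibrated at realistic noise levels — not
that the biological model generating real data is this simple.

## 5. Determinism, problem sizes and limitations

All randomness lives in the generator and is driven by one master seed;
every analysis stage is deterministic, and the pipeline writes byte-identical
outputs on repeated runs over the same inputs (verified by checksum in the
suite). Output CSVs carry a schema version and a configuration fingerprint
(a simple polynomial content hash — collision resistance is not a goal).

The simulation studies in the test suite and acceptance script use the
study's own scale where the property concerns it (5 trees × 2 sites × 5
species × 12–15 campaigns; background lines with n = 30 per species), and a
reduced 3-trees × 8-campaigns grid (~240 twig rows per replicate) for the
repeated power/type-I model fits, which keeps hundreds of mixed-model fits
affordable while leaving the factor structure intact.

Known limitations: the binomial success model treats buds within a twig as
independent given the twig's random effects (overdispersion from correlated
buds within a twig is absorbed only by the tree intercept); the onset rule
reports at campaign resolution, so a collapse between campaigns is dated to
the first campaign that observes it; and with only two campaigns after the
first frost the quadratic date term of the depth model is barely
identified — the model requires at least two campaigns and will warn through
its fit diagnostics rather than refuse.
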