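---
title: "Statistical methods for plate-based CI-suppression screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for plate-based CI-suppression screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciscreen)
```

## The screening problem

Cytoplasmic incompatibility (CI) is a *Wolbachia*-induced reproductive
manipulation: when an uninfected female mates an infected male, most
embryos die before hatching. The screen this package supports feeds
candidate compounds to uninfected females and asks whether a compound
raises the hatch rate of the incompatible cross — chemical suppression of
CI. The readout is the hatch rate, the fraction of laid eggs that hatch.

Each 24-well screening plate carries three conditions of eight wells each,
ten females per well:

* **CI control** — uninfected females × infected males, untreated.
  Hatch rates near 4–14%.
* **CI + treatment** — the same cross with the candidate compound in the
  female's food.
* **Rescue control** — infected females × infected males; the infection in
  the mother restores hatching (~92%), bounding the assay's dynamic range
  from above.

Vial-format experiments (group matings or mating-confirmed single pairs)
use the same data model with one "well" per female or vial, and are
summarised by pooled egg counts rather than per-well replicates.

## Units of analysis

Two summaries of the same records serve different designs:

* the **pooled hatch rate** `sum(hatched)/sum(laid)`, the egg-weighted mean
  of per-well rates — used for vial experiments, where per-female egg
  distributions are not replicated enough to treat each female as a unit,
  and compared between conditions by a chi-square goodness of fit on
  pooled counts;
* **per-well proportions** — used for plate screens, where the well is the
  replicate unit; condition means and standard deviations over wells feed
  the two-sample tests and the Z′ factor. Sample standard deviations use
  the n−1 denominator throughout, the screening-quality convention.

These identities are enforced by tests: the pooled rate equals the
egg-count-weighted mean of per-well rates exactly, and is invariant to
reordering or splitting wells.

## The synthetic-data generator

Real per-well screen data are rarely public, so every downstream stage is
exercised against a generator that reproduces the statistical structure of
a screening plate (`sim_params()`, `simulate_screen()`):

* **Fecundity**: eggs laid per well are Poisson with mean λ, redrawn at
  zero (a well with no eggs carries no rate). The default λ = 150 reflects
  ten females laying over the one-day scoring window.
* **Hatching**: hatched counts are beta-binomial: the well's latent hatch
  probability is Beta-distributed with mean *p* and intraclass correlation
  ρ, then eggs hatch independently at that probability. The Beta
  parameterisation is a = p(1−ρ)/ρ, b = (1−p)(1−ρ)/ρ, so ρ is exactly the
  intraclass correlation and ρ = 0 degenerates to a plain binomial.
  Between-well heterogeneity — female age and condition, feeding, local
  dosing — makes per-well rates overdispersed relative to binomial
  sampling; ρ is the single knob for that spread, giving per-well rate
  variance ≈ p(1−p)(1 + (λ−1)ρ)/λ.
* **Reproducibility**: a root seed expands to per-plate child streams by
  fixed arithmetic (`seed + 1000003·i mod 2³¹−1`), so a dataset is
  bit-reproducible and any single plate can be regenerated independently.

`default_calibration()` fixes the condition means at the midpoints of the
ranges characteristic of a strong CI system — CI control 0.12, treated CI
0.25 (a NaBu-sized effect, roughly a doubling), Rescue 0.92, uninfected
control cross 0.90 — with ρ = 0.002 and λ = 150, five plates of eight
wells per condition. The `"ci-null"` scenario sets the treated mean equal
to the CI-control mean and is the package's negative control: under it the
adaptive comparison's type-I error is verified to sit at the nominal
alpha.

The generator emulates the *statistical* structure only. It does not model
CI cytology (pronuclear timing, chromatin defects), female mortality,
within-well correlation between the ten females, edge effects, or
day-to-day drift between plates; plate effects enter only through
independent per-plate sampling. Passing tests therefore certify the
analysis pipeline under realistic dispersion and effect sizes, not the
biology of any particular screen.

True per-well egg-count dispersion is not something published summaries
pin down; λ and ρ are calibration choices, not estimates. A note on what
this calibration can and cannot deliver: with eight wells per condition,
the sampling noise of an eight-well standard deviation puts an
irreducible spread of about ±0.04 on a single plate's Z′. The calibration
centres plate Z′ near 0.80, inside the 0.76–0.89 window typical of a
high-quality plate assay, but the minimum over five replicate plates
still falls below 0.76 for a substantial fraction of seeds — a property
of small-sample sd estimation, not of the assay mean, and worth
remembering when judging single-plate Z′ values at n = 8.

## Plate QC and dose selection

Plates enter hit scoring only if the pooled CI-control hatch rate is at
most 12% (`qc_gate()`, boundary inclusive, with a 10⁻¹² tolerance so that
rates exactly at the boundary, e.g. 12/100, are not excluded by
floating-point representation). Strong CI in the untreated control is the
within-plate evidence that the incompatible cross worked; the gate is
monotone — lowering any hatched count can never turn a passing plate into
a failing one.

Dose-response tolerability testing (`score_dose()`) grades each candidate
dose over two consecutive six-day windows: a stage (eggs, larvae, pupae)
is defective when its count, pooled within the window, falls 40% or more
below the stage-matched control (boundary inclusive). A dose is `"-"`
when some stage is defective in both windows (a consistent defect),
`"some"` when defects appear only in the late window, `"+"` otherwise.
The loss rule is applied per stage because pooling across stages would
let a surplus at one stage mask a collapse at another. Adult mortality is
observed qualitatively in such assays but has no numeric rule and does
not enter the grade. The screening dose is the highest `"+"` dose
(`select_dose()`), which is invariant to appending higher, non-tolerated
doses.

## The adaptive comparison and hit calling

Plate-screen comparisons are two-sided, two-sample tests on per-well
proportions, selected by a conventional decision path (`choose_test()`):
each group is screened for normality (Shapiro–Wilk) and the pair for
homogeneity of variance (Levene, mean-centered), both at an unadjusted
0.05; then

| normal | homogeneous | test |
|---|---|---|
| yes | yes | Student *t* |
| yes | no | Welch *t* |
| no | yes | Mann–Whitney *U* |
| no | no | bootstrap *t* |

The bootstrap *t* centres each group at its own mean (imposing the null of
equal means while preserving each group's shape and spread), resamples
observations with replacement B = 10,000 times, and refers the observed
Welch statistic to the resampled null (two-sided, with the +1 correction).
Resampling observations rather than residuals is the natural choice when
the two groups are allowed different shapes. B = 10,000 keeps the
Monte-Carlo noise on the p-value below ~10⁻²; the resampled statistics are
computed by vectorised column operations, which matters inside the
sub-sampling loop below. A unit test verifies that on heteroscedastic
normal data the bootstrap p agrees with the analytic Welch p.

Levene's statistic is computed in closed form for two groups (the one-way
ANOVA F on absolute deviations from group means) because it runs on the
order of 10⁵ times inside a power sweep; it is verified against
`car::leveneTest(center = mean)` to 10⁻¹⁰.

**Degenerate inputs.** A zero-variance group defeats both screens. The
comparison flags the pair as degenerate and resolves it by separation:
identical constant groups → p = 1, distinct constant groups → p = 0. This
keeps the sub-sampling loop total — any drawable sub-sample has a defined
p-value — and matches the only sensible reading of complete separation.

**Vial-format comparisons** use the chi-square goodness of fit on pooled
(hatched, unhatched) counts with one degree of freedom, expected counts
taken from a fixed reference rate — the control group's observed hatch
rate. Treating the control as a fixed expectation (goodness of fit rather
than a 2×2 homogeneity test) is numerically inconsequential at the egg
totals involved (hundreds per condition) but matches how such comparisons
are usually reported. Multi-category experiments are judged against a
Bonferroni-scaled alpha (`alpha_policy()`): 0.05/m, with m the number of
data categories in that experiment (six for three-cross comparisons →
0.0083; four for the treatment-vial experiments → 0.0125). m is supplied
per experiment by the caller; no correction is applied across distinct
screened compounds, which are separate experiments.

**Hit calls** (`classify_hit()`) map p-values to Yes / Borderline / No
with a default borderline band of [0.04, 0.05). The band is the narrowest
rule consistent with conventional screen reporting, where p-values a
shade under alpha (0.041–0.047) are flagged as borderline while anything
at 0.013 or below is a clear hit; both thresholds are arguments. Reported
p-value strings parse via `parse_reported_p()`, which maps a bound like
`"< 0.001"` to 0.9× the bound (0.0009) so bounded and exact entries share
one numeric column.

## Z′ and the hit range

Assay quality per plate is the Z′ factor over per-well rates of the two
controls:

$$Z' = 1 - \frac{3(\sigma_{CI} + \sigma_R)}{|\mu_R - \mu_{CI}|}$$

Z′ is positive exactly when the controls' three-sd envelopes do not
overlap and approaches 1 as the envelopes shrink relative to the
separation. Negative values are reported, not clipped — they diagnose
failed plates. The well (not the female, and not pooled eggs) is the
replicate unit, consistent with plotting each well as one point.

A treatment's position between the controls is its affine-normalized mean
(`normalized_score()`): 0 at the CI-control mean, 1 at the Rescue mean.
The "hit range" is the open interval between the CI boundary
μ_CI + 3σ_CI and the Rescue boundary μ_R − 3σ_R; the flag tests the
*treatment mean* (the per-plate average) against those boundaries, since
hit calling operates on condition averages, with individual-well spread
already absorbed into the boundary definition.

## Sub-sampling power analysis

How many replicate wells per condition does a screen need? The package
answers empirically (`min_sufficient_wells()`), mirroring how the
question arises in practice — "how many plates, with how many wells, per
compound?":

1. Replicate plates are paired crosswise (`plate_pairs()`); each pair
   pools its wells per condition (two 8-well plates → 16 wells).
2. For each pair dataset and each k from 3 upward, B sub-samples draw k
   wells per condition **without replacement** (a sub-sample of distinct
   wells — drawing with replacement would duplicate replicates), and the
   full adaptive comparison — including test re-selection — runs on each
   sub-sample at level alpha.
3. The rejection probability per (pair, k) is the rejecting fraction; the
   minimum sufficient k is the smallest k whose rejection probability
   reaches the criterion (default 99.5%) in **every** pair dataset
   simultaneously. The every-pair reading is the conservative resolution
   of "sufficient for all datasets analyzed": a well count is only
   sufficient if no replicate pairing would have missed the effect.

Defaults: B = 2000 sub-samples per (pair, k), bounding the standard error
of a probability estimate near 0.995 at ~0.0016; k sweeps 3 (the minimum
the adaptive tests accept) to the pooled group size (16 for paired 8-well
plates); alpha is the per-resample test level, unadjusted. Each (pair, k)
cell derives its own child seed from the root seed, so estimates do not
depend on sweep order and the whole curve is deterministic given (data,
seed, B). `stop_when_met = TRUE` truncates the sweep at the first
sufficient k when only the minimum is needed.

Rejection probability is non-decreasing in k up to Monte-Carlo noise;
the suite checks isotonicity with B = 5000 and tolerance 0.02, and that
the stricter alpha = 0.01 never needs fewer wells than alpha = 0.05.

## Problem sizes and runtime choices

The shipped tests and the acceptance script run at desk scale, chosen so
the full suite completes in minutes on one core: five simulated plates of
8 wells per condition (the canonical screen format), 10⁴ wells for
generator-recovery checks, 1000 null screens for type-I calibration,
B = 2000 sub-samples per (pair, k) for power sweeps (B = 5000 for the
isotonicity check), and B = 2000–10,000 for bootstrap branches. These
sizes keep Monte-Carlo error well inside the asserted tolerances; larger
B changes nothing but the runtime.

## Known limitations

* The generator draws wells independently; systematic plate or edge
  effects must be injected by the user if needed.
* The Mann–Whitney branch tests distributional shift, not specifically a
  mean difference; with strongly unequal shapes its rejection is not a
  statement about means alone.
* The borderline band and the 0.9× parsing of bounded p-values are
  reporting conventions, configurable but not data-driven.
* Per-female variation within vials is not recoverable from pooled vial
  summaries; vial comparisons therefore rest on pooled counts and inherit
  the usual caveats of count-pooling across heterogeneous females.
* Z′ at eight wells per condition is itself a noisy statistic (spread
  ~±0.04 under the default calibration); judge assay quality on several
  plates, not one.
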