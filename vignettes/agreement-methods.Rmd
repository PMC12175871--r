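---
title: "Agreement methods for ordinal quality instruments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Agreement methods for ordinal quality instruments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prhism)
```

This vignette explains the statistical model behind the package, the choices
made where the methodology was genuinely open, and what the synthetic-data
machinery does and does not tell you about real rating data.

## The setting

A panel of R raters (six in the motivating design: three physicians with more
than ten years of experience, three with less) independently scores a common
set of n videos with two quality instruments and a subjective expert
assessment:

* **PRHISM** — 13 principles, each 0 (completely unmet) to 4 (completely
  met), with a not-applicable option per principle. The sheet score is
  `100 · Σ(applicable scores) / (4 · n_applicable)`, banded 0–25 poor,
  26–50 mediocre, 51–75 good, 76–100 excellent. A separate overall 0–4
  judgment exists purely so agreement can be computed on a single ordinal
  item; it never enters the score.
* **DISCERN** — 15 items plus one overall judgment, each 1–5; total out
  of 80. The *modified* DISCERN score removes the overall item and converts
  the 15 items to a 0–100 scale over the applicable items, making it
  comparable with the PRHISM score. Because items floor at 1, this score
  cannot fall below 20.
* **Expert assessment** — accuracy and potential harm, each 1–5. The original
  tool scores accurate (or nonharmful) information as 1; the package recodes
  `v → 6 − v` so that 5 is always the good end, matching the instruments.

## Agreement statistics

**Weighted kappa.** For two raters on K ordered categories,
`κ_w = (p_o − p_e)/(1 − p_e)` with weighted observed and chance-expected
agreement. The default weights are quadratic, the standard choice for
Likert-type data, where a one-category miss costs little and distant misses
cost a lot; identity weights reproduce unweighted Cohen kappa (used for items
where not-applicable answers break the ordinal structure of the pairwise
table), and linear weights are available. Every result row records the scheme
actually used.

**Standard error.** The non-null large-sample variance of weighted kappa
(Fleiss–Cohen–Everitt form). The exact reference formula used by the original
analysts is not recoverable, so this conventional choice is cross-checked in
the test suite against a 10,000-replicate nonparametric bootstrap on a fixed
table (agreement within 15%) and against the 1/√n replication scaling it must
satisfy. Confidence intervals are normal approximations `κ ± z·se`, reported
untruncated (an endpoint outside [−1, 1] is printed with a note rather than
clipped, so small-n pathologies stay visible).

**Multi-rater agreement.** The study statistic is the mean of all C(R, 2)
pairwise kappas (15 pairs for 6 raters). The pairs share subjects, so they
are strongly dependent; how the original analysis handled that dependence is
not stated. The package's default CI is a delete-one-video jackknife of the
mean-of-pairs statistic: remove video i, recompute all 15 pair kappas and
their mean, and use the jackknife variance of those n leave-one-out means.
This respects the sharing and is what the coverage tests validate. A naive
interval that treats the 15 pair kappas as an independent sample
(`ci_method = "independent"`) is retained behind a flag because its width
(se ≈ 0.02 at the study scale) closely matches the width of the primary CI
reported in the motivating study, whereas the jackknife SE is about three
times larger — a discrepancy users should be aware of when comparing against
published agreement studies. The jackknife leave-one-out values are computed
by O(1) updates of the table marginals, so the full analysis stays fast at
simulation scale.

**Degenerate tables.** A pair whose expected agreement is 1 (both raters
concentrated on the same single category) has undefined kappa; such pairs are
excluded from the mean with a warning, never imputed. NA ratings are dropped
pairwise within each pair, not listwise across raters; the ICC alone deletes
listwise, as its two-way layout requires complete rows.

**Cross-instrument kappa.** Validity compares ratings on different supports
(PRHISM overall 0–4 vs expert 1–5; the 4-level band classification vs a 1–5
rating). Each scale is shifted by an integer so its support starts at 0 and
the union of supports forms the common ordered category set. Distances are
never rescaled: a one-step disagreement costs the same whichever instrument
it came from. Whether the original analysis aligned scales the same way is
unknown; this choice is the least-distorting one available.

**ICC.** Two-way random-effects, absolute-agreement, single-rater ICC
computed directly from the mean squares of the subjects × raters layout, with
the McGraw–Wong F-based interval. The test suite checks the mean squares
against `stats::aov` and the estimate against a variance-ratio simulation.

**Interpretation.** Landis–Koch bands (<0 no agreement, 0.00–0.20 slight,
0.21–0.40 fair, 0.41–0.60 moderate, 0.61–0.80 substantial, 0.81–1.00 almost
perfect), applied after rounding half-up to two decimals so the printed
band edges behave as printed. Kappa ≥ 0.61 is additionally flagged as
"sufficient", the conventional adequacy threshold. Score bands round half-up
to the nearest integer before banding for the same reason; note neither
instrument's score formula can actually produce a .5 value adjacent to a band
edge at realistic item counts.

## The copy model and the power simulation

Sample size for an agreement study needs a generative model with a
controllable true kappa. The package uses a latent **copy model**: each video
has a true category T drawn from a marginal π over the 5 ordinal categories;
each rater independently reports T with probability θ and otherwise an
independent draw from π. The pairwise joint distribution is available in
closed form, and a short calculation shows the population weighted kappa is
exactly θ², for every weight scheme and every nondegenerate marginal
(`p_o = θ² + (1 − θ²) p_e`). `calibrate_theta()` still solves
`expected_kappa(θ) = κ_target` by bisection (to |Δκ| ≤ 1e−6) rather than
hard-coding √κ, so alternative rater models can plug into the same interface.
Raters are exchangeable (a single θ) by default — real panels are plainly
heterogeneous, and `simulate_ratings()` accepts a per-rater θ vector, but the
power analysis keeps the exchangeable default because nothing in a design
stage pins down individual rater quality.

`estimate_power()` mirrors the analysis pipeline inside the simulation loop:
per replicate it computes the pairwise mean kappa and its jackknife SE, then
the two-sided z-test `z = (κ̂ − κ₀)/se` at level α. Replicates with a
degenerate pair are redrawn, capped at 5% of the total (beyond that the
configuration itself is judged degenerate and the run aborts with a
diagnostic). A per-pair-then-pool SE variant (`se_method = "pooled_pairs"`)
is kept behind a flag for comparison with analyses that treated pairs as
independent. `find_min_n()` estimates power on a grid of video counts,
applies isotonic regression (power is monotone in n up to Monte-Carlo
noise), and returns the smallest grid point whose smoothed power reaches the
target.

Two calibration facts the test suite enforces: at κ_true = κ₀ the jackknife
z-test rejects at close to its nominal α (the size is slightly above nominal,
within Monte-Carlo tolerance at 2,000 replicates), and the 90% jackknife CI
of the pipeline's primary estimate covers the generating kappa in at least
85% of 200 seeded synthetic studies at each of κ ∈ {0.3, 0.61, 0.8}. The
independent-pairs variant fails the size check badly (rejection rate ≈ 0.5
at the null in the same configuration), which is the quantitative reason the
jackknife is the default.

**The pilot marginal.** The motivating study calibrated its simulation on
the overall-quality distribution from a 50-video pilot, published only as a
histogram figure. `pilot_marginal_synthetic()` is a clearly-labelled
synthetic stand-in — unimodal, centred between categories 2 and 3, consistent
with the mid-range mean quality the study reports — and every power figure
computed with it is conditional on that choice. Under this model the
55-video, 6-rater design reaches roughly 31% power (jackknife SE; about 70%
even with the independent-pairs SE) for detecting κ = 0.61 against κ₀ = 0.53
at two-sided α = 0.10, far below the 80% the original design calculation
claimed. The implied SE of the study's own published primary CI (≈ 0.018)
matches the independent-pairs width, suggesting the original simulation both
treated pairs as independent and used a rater model with less off-diagonal
scatter than the copy model. The package reports what its stated model
computes rather than reverse-engineering a configuration that reproduces the
published 55.

## The synthetic study generator

`generate_catalog()` emulates the selected-video table: multinomial source
categories over eight uploader types (defaults are the published proportions;
categories 1–4 count as reliable sources), log-normal length / views /
months-since-posting bracketing the published ranges (the true shapes are
unknown and explicitly arbitrary), and a latent quality in [0, 1] with a
positive logit shift (default 0.8) for reliable sources. `apply_exclusions()`
implements the numbered exclusion list (language, <3000 views, <60 s,
irrelevant, no audio, shorts, duplicate, advertisement) with
first-criterion-wins tallying; views of exactly 3000 and length of exactly
60 s are kept, reading "fewer than" and "shorter than" strictly.

`generate_ratings()` turns a catalog into a full multi-instrument rating set.
Truth categories derive from latent quality through fixed quantile
thresholds, so the truth marginal is controlled by π independently of the
agreement parameter. Overall-quality ratings for each instrument come from
the copy model with θ calibrated to the requested kappa; the 13 PRHISM items
are the rater's own overall plus rounded-Gaussian jitter clipped to 0–4 (with
a per-principle not-applicable probability, default 0.10 — a placeholder, as
item-level NA frequencies are unpublished); the 15 DISCERN items likewise on
1–5; expert accuracy and harm are jitter around the truth category mapped to
1–5, already on the recoded orientation. With zero jitter, zero NA
probability and agreement 1, every rater reproduces the truth exactly and
every kappa in the pipeline equals 1 — the end-to-end identity the test suite
exercises.

What the generator does *not* emulate: rater-specific severity and drift over
the rating session, correlation between the not-applicable mechanism and
video content, ordinal response styles (end-aversion, category clumping), or
any dependence of expert accuracy on factors other than latent quality.
Passing tests therefore demonstrate the statistical machinery is correct and
calibrated under a clean exchangeable model, not that any instrument is
reliable on real videos.

## Problem sizes and numerical choices

The test suite and the acceptance script scale their simulations to desk
scale: 2,000 replicates for the size check (Monte-Carlo se ≈ 0.007), 10,000
for the power figures at the 55-video design, 1,000 per grid point for the
power curve, and 200 seeded studies per kappa for CI coverage. Bisection for
θ stops at |Δκ| ≤ 1e−6; kappa is declared degenerate when 1 − p_e falls
below √ε (≈ 1.5e−8); the jackknife is computed in exact arithmetic via
marginal updates, verified against brute-force recomputation. All generators
take explicit seeds, restore the caller's RNG state, and identical seeds give
byte-identical datasets, result CSVs and reports.

## Known limitations

* The jackknife CI is asymptotic; at very small n (< 10 videos) its coverage
  is untested and the normal approximation for kappa itself is dubious.
* The copy model's population kappa being θ² means the marginal π affects
  only estimator *variance*, not the target value; rater models where the
  target depends on π would need their own `expected_kappa`.
* The modified DISCERN score has no published banding; the PRHISM bands are
  reused for its classification analyses and flagged in the output.
* Strata use physician-years > 10 as senior, so a rater with exactly 10
  years is junior; published phrasing is inconsistent on this boundary and
  the report notes it.
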