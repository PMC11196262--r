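---
title: "Methods: the postural stroke-volume challenge pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the postural stroke-volume challenge pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(posturesvr)
```

## The clinical problem

Deciding whether a spontaneously breathing, hemodynamically *stable*
patient will raise their stroke volume (SV) after an intravenous fluid
bolus is hard precisely because everything about the signal is small:
passive leg raising barely moves SV in this population, respiratory
variation corrupts beat-to-beat Doppler readings, and the SV changes that
distinguish mild hypovolemia from euvolemia live in single-digit
percentages. `posturesvr` implements an analysis pipeline for a protocol
that attacks all three problems at once:

1. a **60° upper-body elevation (UBE) → supine transition** as the preload
   challenge (a much larger, steadier preload shift than leg raising);
2. an SV proxy built from **end-expiratory maxima** of the left-ventricular
   outflow tract velocity–time integral (VTImax), excluding inspiratory
   beats entirely;
3. a **robust order-statistic estimator** — the mean of the central five of
   9–17 accepted readings per stage — to reject readings corrupted by
   Doppler-gate misalignment.

The five-stage protocol is UBE → supine → UBE → supine → supine after a
500–700 mL saline bolus. The repeated UBE/supine pair exists to check
measurement consistency; the headline positional index comes from the
first pair, and the fluid-induced index from the last supine stage versus
the post-fluid stage.

## The measurement statistic

Per protocol stage, the respiratory phase of each beat is tracked and the
largest VTI among beats within ±0.10 of end-expiration (phase 0) is kept,
one reading per respiratory cycle (`select_end_expiratory_maxima()`). The
phase window of 0.10 is a package default: the protocol defines
end-expiration qualitatively, and a tenth of a cycle either side is what a
sonographer can realistically gate by eye.

Given $n \in [9, 17]$ accepted readings, the stage estimate is

$$\hat v = \tfrac15 \sum_{i=k+1}^{k+5} x_{(i)}, \qquad k = \frac{n-5}{2},$$

the mean of the central five order statistics (`central_five_mean()`).
Discarding the $k$ highest and $k$ lowest readings (2–6 per side across
the protocol's 9–17 range) rejects readings taken with the Doppler gate
too close to or too far from the aortic valve. Because misalignment can
only *deflate* a VTI tracing, the estimator tolerates up to $k$ corrupted
readings without leaving the range of the clean ones. An even reading
count (possible in user CSVs, not under the protocol's arithmetic) is
handled by first discarding the single reading farthest from the overall
median, ties going to the larger value, then applying the odd-$n$ rule.
Peak velocity readings get the identical trimming scheme.

The comparator the protocol improves upon — the plain mean over five
consecutive cardiac cycles, inspiratory beats included
(`conventional_consecutive_mean()`) — carries the full respiratory
modulation into the estimate; under the default noise model its RMSE is
roughly an order of magnitude larger than the trimmed estimator's (both
are recomputed by `scripts/acceptance.R`).

## Index algebra

All changes are **symmetric percent changes**,
$100\,(x_{to}-x_{from})/\{(x_{to}+x_{from})/2\}$, bounded in $(-200,200)$
and antisymmetric in their arguments. The plain ratio form
$100\,(x_{sup}/x_{ube}-1)$ is linked exactly via
$r = 200c/(200-c)$ (`symmetric_to_ratio_pct()`), so thresholds stated on
one scale can be restated on the other (a symmetric cut-off of 11.8%
corresponds to a ratio increase of 12.54%). Collapsibility of the internal
jugular vein (IJV) uses the same symmetric normalisation of the
respiratory max–min swing and is scale-invariant, so diameters and areas
are treated identically.

Thresholds (`default_thresholds()`): a positional or fluid-induced change
≥ 7% flags suspected mild hypovolemia and gates the fluid challenge in
patients; fluid responsiveness is a fluid-induced change ≥ 10%. All
comparisons are inclusive (ties classify positive). The repeat-consistency
tolerance defaults to 5% — deliberately below the 7% screen, so that
measurement inconsistency can never by itself mimic a positive screen.
The positional IJV change is reported supine-minus-elevated (positive when
the vein distends on lying down) by default; the literal
elevated-minus-supine orientation is available behind the
`sign_convention = "formula"` flag, because the two published statements
of this index conflict in sign and the package refuses to guess intent.

## The synthetic cohort generator

No subject-level data accompany the protocol, so the package ships a
mechanistic generator (`generate_cohort()`) whose role is to exercise the
estimator and pipeline under the study's stated conditions — not to be a
cardiovascular simulator of record.

**Physiology.** Each subject carries a saturating Frank–Starling curve
$VTI(p) = \text{plateau}\,(1-e^{-p})$, the simplest strictly increasing,
concave, two-parameter form. Preload is in arbitrary units: euvolemic
supine baseline 2.30 (between-subject SD 0.05), positional shift
$\delta = 0.31$ (SD 0.03) for the 60° elevation, and $5.1\times10^{-4}$
preload units per mL of saline. These three constants are calibrated so
that a euvolemic subject's noiseless positional change sits near 4% and
the fluid-induced change near 2.9% at a 600 mL bolus — both comfortably
under the 7% screen, matching the study's healthy-cohort observation that
no volunteer reached 7%. Patients draw a true deficit from an exponential
(rate 2.6) truncated at 1.8 units: the cohort is hemodynamically stable
with at most mild hypovolemia, and untruncated tails would collapse
preload entirely. A per-subject lognormal bolus-effectiveness factor
(SD 0.35 in patients, 0.12 in well-hydrated volunteers) models how much of
the infused volume actually reaches the central circulation; it is what
decouples the fluid response from the positional response and brings the
simulated discrimination (AUC ≈ 0.95, $R^2$ ≈ 0.78) down from the
near-perfect coupling a noise-free deficit model would give.

**Measurement noise** (`noise_params()`): a smooth respiratory dip of 15%
at peak inspiration (zero at end-expiration, $\sin^2$ bump); sporadic
misalignment deflations, 4% per beat, multiplying the beat by 0.78–0.95 —
strictly downward, since a drifted gate can only under-read; and 1.2%
multiplicative jitter. Respiratory rate 15/min and heart rate 70/min keep
subjects inside the protocol's sinus-rhythm stability window. The
misalignment rate is the binding calibration: it is set low enough that a
45-volunteer cohort almost never shows a spurious ≥ 7% change (the
acceptance suite requires this in ≥ 95% of 100 seeds) while still
averaging ≥ 2 deflation events per 13-reading recording. One consequence,
accepted deliberately: the "inconsistent repeat" exclusion becomes rare
(0–1 per 215 patients), rarer than in the real cohort — the two published
conditions cannot both be matched by one homogeneous noise level.

**What the generator does not emulate:** arrhythmia, ventilator
interaction, intra-abdominal pressure, operator learning effects, drift of
true physiology between stages, and the real joint distribution of IJV
geometry with volume status (IJV channels are weak-signal by construction,
mirroring the finding that collapsibility discriminates poorly in
spontaneous breathing). Passing tests therefore certify the *statistical
machinery* under a plausible noise structure, not clinical performance on
real patients.

## Diagnostics

AUC is the two-sample rank statistic computed from midranks
(`auc_rank()`), exactly equal to the all-pairs probability with ties
counted half. ROC cut-offs sweep the distinct observed scores under the
inclusive orientation (positive when score ≥ cut-off); the reported
cut-off maximises Youden's $J$, ties resolving to the largest (most
specific) threshold, which for separated groups is the lowest observed
positive score. Group summaries are medians with quartiles under the
$p(n+1)$ weighted-average convention (`quantile type 6`), matching common
clinical statistics software. Mann–Whitney p-values use the tie-corrected
normal approximation with continuity correction (cohort sizes here are
~100); the logistic fit is ML via IRLS with Wald intervals, and perfect
separation is flagged on the result rather than raised as an error.

The split-normal sampler (`quantile_split_sampler()`) reconstructs a
distribution from a printed "median (q25, q75)" summary exactly at those
three quantiles — on the log scale for strictly positive skewed summaries
(SV changes), linear for summaries whose lower quartile approaches zero
(peak-velocity changes). Reconstructed this way, the reported responder /
non-responder summaries imply population AUCs of ≈ 0.94 (SV) and ≈ 0.74
(PV); the acceptance suite checks these against the reported 0.958 and
0.804 within a 0.10 stochastic band, the residual gap measuring how much
of a distribution three printed quantiles pin down.

## Numerical and degenerate-input choices

Strictly positive measurements are enforced at every index boundary
(domain errors, not NaN). `central_five_mean` rejects $n<9$ or $n>17$ as
protocol violations. Reading selection errors out below 9 complete
respiratory cycles and caps at 17 readings by dropping the earliest
cycles. A cohort of size zero is an empty cohort, not an error; a study
with no responder/non-responder contrast returns empty diagnostics with a
warning, not a crash. Preloads at or below a floor of 0.05 units raise a
degenerate-subject error. All simulation flows through R's RNG so a fixed
seed gives byte-identical cohorts and output files.

## Problem sizes used by the test and acceptance suites

Estimator–oracle equivalence runs 10,000 random instances; the RMSE
comparison and the healthy-calibration check use 1,000 simulated
recordings and 100 seeded 45-volunteer cohorts respectively; parameter
recovery regresses 500 patients; the quantile-matched AUC reproduction
uses 2×10⁵ Monte-Carlo draws. These sizes give Monte-Carlo error well
inside each check's tolerance while keeping a full run around a minute.

## A worked run

```{r study, eval = FALSE}
res <- run_study(cohort_config(seed = 42))
res
res$summaries[, c("index", "nonresponder", "responder", "auc")]
```

`run_study()` prints the screening flow (screened = excluded + challenged,
by exclusion reason), the responder split among the challenged, the AUC
and Youden cut-off of the positional change, and the $R^2$ linking
positional to fluid-induced changes. `write_study_result()` emits the
per-subject panels, screening table, group summaries and diagnostics as
CSV/JSON; `scripts/acceptance.R` recomputes the headline quantities from
scratch for any seed.
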