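---
title: "Methods: ex vivo drug-sensitivity screening analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ex vivo drug-sensitivity screening analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exscreen)
```

This vignette documents the models, parameter choices, numerical
conventions and known limitations behind the pipeline. The package analyzes
384-well ex vivo drug screens of primary cells: each plate carries DMSO
vehicle wells (negative controls, defining 100% viability), benzethonium
chloride wells (positive controls, defining 0%), and titrations of single
drugs or combinations, read out by ATP luminescence after exposure.

## Normalization and plate QC

Viability is an affine rescaling of the raw signal anchored on the per-plate
control means, `V = 100 (s − μ_pos)/(μ_neg − μ_pos)`. Two deliberate
conventions:

* **Viability is not clamped before fitting.** Values slightly above 100 or
  below 0 are informative about the noise around the asymptotes; clamping
  them would bias asymptote estimates. Inhibition used by Bliss scoring
  *is* clamped to [0, 1], because the independence model composes
  probabilities.
* **Control summaries use the mean and sample SD**, matching the standard
  Z′-factor definition `Z' = 1 − 3(σ_pos + σ_neg)/|μ_neg − μ_pos|`. The
  usability floor defaults to Z′ ≥ 0.4 — below the ~0.6 typically observed
  in well-behaved screens of this kind but above the conventional 0.5 − ε
  "marginal assay" region; plates failing the gate are reported, never
  silently dropped, and can be forced through with `override_qc`.

**Order of QC and curation.** The outlier screen runs *before* the Z′ gate,
and the gating Z′ is computed on curated controls (the raw Z′ is reported
alongside). Curation exists to remove exactly the dispensing/edge artifacts
that inflate control SDs; gating on the raw Z′ would reject plates whose
only defect is a handful of flaggable control wells. On simulated plates
with a 2% outlier rate this distinction moves the mean Z′ from ≈0.57 to
≈0.85 and plate usability from ~2/3 to 44/44.

## The automated outlier screen

Manual curation is replaced by a deterministic rule, scored against
simulations with labeled outliers. Design rationale:

1. **Replicate rule** (groups of ≥ 3 wells with an identical treatment):
   flag `|V − median| > max(3·mad(V), 15)` percentage points. The
   15-point floor prevents flagging tight replicate groups whose MAD is
   near zero by chance.
2. **Control log-signal rule** (control groups of ≥ 8 wells): flag
   `|log s − median(log s)| > max(3·mad(log s), log 1.5)`. The noise is
   multiplicative, so the log scale is homoskedastic; a ×3 positive-control
   artifact is ~22σ here but only ~4 viability points — invisible to rule 1.
3. **Residual rule** (single-agent titrations, ≥ 5 points at ≥ 4 doses):
   a naive "fit, then flag |standardized residual| > 3" rule fails by
   *masking* — one ×3 well drags the fitted top asymptote to its bound and
   inflates the robust residual scale, hiding itself (measured sensitivity
   0.61). The implemented rule first sets aside duplicate dose groups whose
   within-pair spread is discordant with the series' robust pair-noise
   estimate (4.5σ, relative floor 0.2), fits the preliminary curve to the
   concordant points only, then adjudicates every point against that clean
   fit (3σ, residual scale ∝ max(predicted V, 5) with a 2-point absolute
   floor), with one refit pass. Measured on 200 labeled plates (2% outlier
   rate, ×3 scale, 5% CV): sensitivity ≈ 0.98, false-flag rate ≈ 0.005.

Flagged wells are excluded from fits but never deleted.

## Concentration–response model

The four-parameter log-logistic model
`V(x) = c + (d − c)/(1 + exp(b(ln x − ln e)))` is fitted by bounded
Levenberg–Marquardt least squares. Choices that matter:

* **Bounds** keep asymptotes identifiable on 6-point data: bottom ∈
  [−20, 50], top ∈ [50, 150] (% viability), slope ∈ [0.1, 10], midpoint
  within the tested range ± 2 decades.
* **Multi-start**: midpoint initialized at the lowest, geometric-mid and
  highest tested dose, crossed with bottom starts at `min(V)` and 0 — the
  latter matters for weak responders whose observed minimum sits above the
  bottom bound and would otherwise start (and stall) pinned at it. Slope
  starts at 1, asymptotes at the observed extremes.
* **Convergence failure is operational**: solver failure, non-finite
  parameters, or a midpoint pinned at a bound without beating the constant
  model. On failure the logistic model is refitted on the log10-dose axis
  (midpoint in log10 nM); in practice the fallback is rare (0% of 1320
  cohort fits at 5% noise).
* **Degenerate inputs**: identical responses yield a constant curve
  (top = bottom = mean, converged); < 3 distinct doses is an error; exactly
  3 distinct doses fits a reduced 2-parameter model with asymptotes fixed
  at 0/100.

IC values solve `I(x) = level` on the fitted curve, restricted to the
tested range extended one decade per side; beyond that the value is
reported as not reached rather than as a wild extrapolation. The
cohort-level priming concentration is the **geometric mean of reached
IC20s** (IC values are log-scale quantities; non-reaching samples are
excluded and counted). Arithmetic averaging would let one resistant sample
dominate the priming dose.

## The drug sensitivity score

DSS integrates the clamped inhibition above an activity threshold `t`
(default 10% inhibition) on the log10-dose axis and normalizes by the
maximal attainable area `(100 − t)(x_max − x_min)` — a DSS type 1 variant
with no logarithm-of-upper-limit divisor anywhere. Integration uses a
fixed 1024-point trapezoid grid rather than a closed-form antiderivative:
the grid is branch-agnostic across the LL4/L4 models and the clamp's kinks,
and it agrees with a 10⁵-point reference quadrature to < 10⁻³ DSS units
over random curves (enforced by test). Inhibition is clamped to [0, 100]
inside the integral so growth stimulation cannot create negative area; DSS
therefore always lies in [0, 100]. Efficacy bands: low [0, 10],
intermediate (10, 40], high (40, 100].

For the 4×4 triple design, a curve is fitted to each *line* of the matrix
and the per-line DSS averaged. Row-wise orientation (drug B titrating
within each drug A level) is the default, with column-wise available via a
flag — the averaging direction is a convention, not inferable from the
design itself, and the two differ when the matrix is asymmetric.

## Bliss synergy

Per non-zero dose pair, the score is
`100·(f_obs − (f_A + f_B − f_A f_B))` percentage points; the synergy sum is
its sum over the matrix (mean × 16 for the 4×4 design) and classification
is strictly `score > 0` — no noise band, matching how screening reports
call synergy.

**Triple design: conditional two-way Bliss.** The background drug is held
at one fixed dose in every cell, so a three-way attribution is
unidentifiable from this design. All fractions (observed and monotherapy)
are therefore conditioned on the background-alone baseline:
`f|bg = 1 − (1 − f)/S_bg`. With this convention a simulated exactly
independent matrix scores identically zero, and an injected survival shift
δ is recovered as 100·δ points per cell.

**Monotherapy source.** Fractions default to the zero-dose margin wells of
the same plate; fitted single-agent curves can substitute when margins are
absent. Fractions are built from unclamped viability, averaged over
replicates, conditioned, and clamped once at the end — clamping per well
would truncate noise asymmetrically near the bounds.

**Known small-sample bias.** With 2 replicate margin wells at 5% CV, the
near-zero low-dose monotherapy fractions truncate at 0, inflating the Bliss
expectation in the low-dose corner; the recovered mean excess for an
injected δ = 0.1 is ≈ 8.5 points rather than 10 (stable across seed sets).
This is a property of clamped fraction estimates at this replicate depth,
not of the scoring identity (the noiseless recovery is exact); it is left
uncorrected because any de-truncation would trade bias for invalid
(negative) probabilities in the independence formula.

## Cohort clustering and group comparison

Samples × treatments DSS matrices are clustered with Euclidean distance and
Ward linkage pinned to the squared-Euclidean `ward.D2` criterion (merge
heights are then monotone; the plain `ward.D` variant is not equivalent).
DSS values share the 0–100 scale, so rows are clustered unscaled by
default; z-scoring is behind a flag. Missing cells are imputed with the
treatment-wise median (reported), because dendrograms need complete
vectors. The cluster count `k` is left to the user: cut heights are
data-dependent and no universal rule applies. Two-group DSS comparisons use
the Mann–Whitney U test — exact enumeration when the combined n ≤ 12 and
there are no ties, the tie-corrected normal approximation otherwise.

## The simulator: what it emulates, and what it does not

Ground truth is drawn from the same log-logistic family the fitting stage
estimates: per drug, IC50 log-uniform over 1–1000 nM, Hill slope lognormal
around 1 (sdlog 0.25), top 100%, bottom uniform over 0–20% (primary-cell
ATP screens typically plateau above complete kill). Cohort heterogeneity
multiplies each sample's IC50s by a lognormal factor (sdlog 0.5, ≈ 3-fold
spread); the two-group mode adds a stated IC50 fold-shift on half the drugs
for clustering recovery tests. Noise is multiplicative lognormal on the raw
signal with mean exactly 1 (luminescence scales with cell number; signals
stay non-negative); every well shares the same background fraction of the
negative-control signal (default 0.02), which is exactly the component
control-based normalization removes — with zero noise the
normalize→fit→DSS path recovers ground-truth DSS to < 0.1 units, by
construction, and the tests enforce it. Outlier wells multiply the signal
by 3 with the stated probability and keep their labels. Replicates default
to 2 for designed plates and 1 for the 30-drug cohort plates (180 treated
wells + 32 controls per 384-well plate).

Deliberately not modeled: spatial plate effects (edge evaporation,
gradients, B-score-type corrections), cell-growth kinetics over the
exposure window, drug-specific noise, and non-sigmoid (biphasic) responses.
Passing recovery tests therefore demonstrates correctness of the analysis
under the stated noise model — not robustness to spatial artifacts or
model misspecification on real plates.

## Problem sizes used by tests and the acceptance script

Chosen to make every stochastic check stable under reseeding while keeping
the default run short: 100 random curves for the DSS quadrature oracle, 200
noisy curves for IC50 recovery, 100 seeded matrices for synergy recovery,
200 labeled plates for the outlier screen, 20 seeded 16-sample cohorts for
cluster recovery, and one full 44-sample × 30-drug cohort (1320 curves) for
end-to-end determinism and runtime (≈ 20 s on one CPU).
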