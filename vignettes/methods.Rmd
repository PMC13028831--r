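---
title: "Models, parameters and design choices in echinoNMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, parameters and design choices in echinoNMR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(echinoNMR)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the tunable parameters and their
defaults, what the synthetic generator does and does not emulate, and the
design choices made where the design was genuinely open. It states no
empirical result that the test suite does not itself compute.

## 1. The analytical setting

One-dimensional ¹H NMR spectra of gonad extracts come in two fractions.
Polar (aqueous buffer, referenced to TSP at 0.00 ppm) spectra carry the
low-molecular-weight metabolome — amino acids, osmolytes, quaternary
amines, nucleotide derivatives — as sharp multiplets across 0.8–9.2 ppm.
Apolar (CDCl₃) spectra are dominated by lipid acyl-chain motifs: terminal
methyls near 0.88/0.97 ppm, the methylene envelope near 1.3 ppm, allylic
and bis-allylic methylenes, α-methylenes to the carbonyl, glycerol
backbone signals and olefinic protons. The package consumes processed
frequency-domain two-column text exports on a common 11.0 to −0.5 ppm
window; FID processing (phasing, apodization, Fourier transform) is
upstream and out of scope.

## 2. Polar arm: PLS-LDA with NIPALS

Class labels are coded −1 (male) / +1 (female); this convention matters
because the LDA threshold and the sign of score plots depend on it.
Columns are mean-centred, and optionally scaled by the column standard
deviation ("auto") or its square root ("pareto"); scaling statistics are
always computed on training samples only and reapplied to held-out data.

Each NIPALS iteration computes a weight vector `w ∝ X'y` (unit norm),
scores `t = Xw`, loadings `p = X't/t't`, `q = y't/t't`, then deflates both
`X` and `y`. `r2x[a] = t't·p'p / ||X₀||²` and `r2y[a] = t't·q² / ||y₀||²`
account for the captured variance per latent variable; scores are mutually
orthogonal by construction and the cumulative sums cannot exceed 1. For a
univariate response, the fitted regression vector after A components has a
closed-form characterisation as the least-squares solution restricted to
the Krylov subspace span{X'y, (X'X)X'y, …}; the test suite uses that
independent route as an oracle at 10⁻⁸.

The discriminant on the scores uses the pooled within-class covariance
with empirical priors (the cohort is unbalanced, 23/14, so priors are not
flat), plus a 10⁻⁸·tr(S) ridge so near-degenerate score covariances never
break a cross-validation fold. `MASS::lda` agrees with this boundary on
well-posed inputs and serves as a cross-check in the tests, not as the
implementation.

Validation: stratified k-fold CV (default k = 7, so every fold keeps both
sexes at the 23/14 cohort shape) and MCCV (default 500 random stratified
80/20 splits; the pipeline default is 200 to keep full runs brisk). The
per-LV error curve pools held-out predictions; `optLV` is the *smallest*
LV count attaining the minimal error — a parsimony tie-break, chosen
because nothing in the validated-complexity convention distinguishes ties.
VIP follows the standard y-variance-weighted formula, so mean(VIP²) = 1
identically.

## 3. SPA and the COSS ranking

SPA asks, per variable: does destroying this variable's information in
held-out samples degrade prediction? Each of `n_iter` (default 1000)
iterations draws a stratified 75% sample subset and `q` variables
(`ceiling(sqrt(V))` bounded to [5, 15]), autoscales on the sub-training
set, fits an inner 2-LV PLS-LDA (two LVs being the validated complexity
of the full model), and records the out-of-subset error twice — intact,
and with the variable's held-out values permuted. Permuting only the
test partition keeps the normal/permuted pair on the *identical*
sub-model, which isolates the variable's predictive contribution.
The per-variable p-value is the one-sided Mann–Whitney probability that
permuted errors exceed normal errors; `COSS = −log10(p)` with a 10⁻³⁰⁰
clamp (finite precision of the decadic log). A variable that is never
sampled is an error instructing a larger `n_iter`, never a silent `NA`.

Two calibration facts shape the defaults. First, with ~150 inclusions per
variable the Mann–Whitney comparison resolves p-values down to ~10⁻¹⁸, the
magnitude printed for dominant markers. Second, under a pure-noise cohort
the selected fraction at α = 0.05 stays near α (the acceptance suite
measures it across 20 replicate null cohorts); error values are heavily
tied, so the tie-corrected normal approximation is the operative branch.

## 4. Mann–Whitney testing

`mann_whitney()` wraps `stats::wilcox.test`: exact enumeration p-values
when `n1 + n2 ≤ 20` with no ties, mid-rank normal approximation with tie
correction otherwise, with the branch recorded in the result. The exact
branch is verified in the tests against a full `C(n1+n2, n1)` enumeration
oracle for every tie-free size up to `n1 + n2 = 12`. Boxplot summaries use
type-7 (linear interpolation) quartiles and 1.5 × IQR whiskers clipped to
the most extreme inlying data points.

## 5. Apolar arm: balance equations, QC, benchmarks

Region windows (ppm): A 0.93–1.00, B 0.83–0.93, C 1.20–1.40, D 1.55–1.72,
E 1.95–2.15, F 2.28–2.36, F′ 2.37–2.40, G 2.70–2.90, H 4.05–4.35,
I 5.20–5.30, J 5.30–5.45. Only F′ has an exactly specified literature
window; the others are anchored to the approximate motif positions above
and are configurable. J is placed flush against I rather than overlapping
it, which avoids double-counting the TAG sn-2 glycerol proton; the
historical nine-equation scheme ties H/I into a triglyceride correction,
but since its coefficients are not reprinted in full, this package solves
the reduced, testable system below and keeps H/I as reported integrals.

With per-chain proton multiplicities from one shared stoichiometry table
(3 terminal-methyl protons per chain, 4 allylic protons per unsaturated
chain, 2 F′-window protons per DHA chain, 2 olefinic protons per double
bond): `T = (A+B)/3`, `ω₃ = 100·A/(A+B)`, `h = 100·(F′/2)/T`,
`n = 100·(E/4)/T`, `s = 100 − n`. Sharing the table between the generator
and the solver makes correctness testable independently of any historical
coefficient set: a wrong multiplicity breaks the round trip immediately.
Integration is plain trapezoid on the native grid — no peak fitting — so
indices are invariant to overall intensity scaling by construction.

QC never throws; it flags: any index outside [0, 100]; `h > ω₃`;
`ω₃ > n`; any negative region integral; and `J/2 < E/4` (fewer olefinic
proton-pairs than unsaturated chains). Flagged spectra are excluded from
summaries, and the QC log names each violated constraint. Batch summaries
report median/IQR per index, overall and per sex, exact two-sided
Mann–Whitney p-values, and a benchmark block placing the batch against
fish-oil reference constants (DHA 7.0–19.2 mol%, median ≈ 14.0; ω-3
20.9–35.7 mol%, median ≈ 26.7).

## 6. The synthetic generator: what it emulates, what it does not

Polar spectra are sums of Lorentzian multiplets (default HWHM 0.003 ppm ≈
1.2 Hz at 400 MHz, matching mild exponential line broadening on natural
linewidth; doublets 1:1, triplets 1:2:1, unresolved multiplets as 5-stick
binomial clusters at J/2 spacing, default J = 7 Hz = 0.0175 ppm), plus a
TSP singlet at 0.00 ppm, an optional low-order polynomial baseline
(default amplitude 0 — real spectra are baseline-corrected upstream) and
additive Gaussian noise. Concentrations are strictly positive:
`base_conc · 2^(sex_log2fc·[female]) · LogNormal(cv = 0.3)`. The default
panel places ~20 metabolites at shifts from the curated table; the seven
with documented discriminant behaviour (glycine, alanine, creatine,
betaine, TMAO, histidine, lysine) carry |log2FC| between 0.5 and 1.0.
No absolute concentrations or effect sizes are published for this system,
so these magnitudes are explicit placeholders that reproduce the
qualitative ranking structure — power results on synthetic cohorts
calibrate the *machinery*, not the biology. The cohort defaults (23 males,
14 females; per-sex biometrics means/sds for diameter, height, weight,
gonad weight, GSI) mirror the published cohort summary.

Apolar spectra render each diagnostic region as a single narrow Lorentzian
(HWHM 5 × 10⁻⁴ ppm) whose integral *inside its own window*, computed by
the same trapezoid rule on the same grid the solver uses, is normalized to
the stoichiometric target area. The generator's contract is therefore
"window integral equals stoichiometric area"; the only residual round-trip
error is cross-window tail leakage of order 0.1 mol%, which is why the
suite asserts the `A/(A+B) = ω₃/100` identity at 0.2 mol% and full
round trips at 0.5 mol%. What the generator does not emulate: time-domain
acquisition artefacts, phase/baseline distortion, peak-position drift
between samples, ¹³C satellites, and realistic crowded-region overlap in
the apolar fraction. Passing tests therefore demonstrate correctness of
windowing, integration, solving, QC, modelling and selection — not
robustness to every pathology of real spectra.

## 7. Numerical choices and degenerate inputs

* Lorentzian evaluation is truncated beyond 500 half-widths (< 0.13% of
  area); area-ratio contracts are unaffected.
* TSP referencing requires a genuine local maximum within ±0.05 ppm of 0;
  ties break to the most downfield candidate, deterministically.
* Peak heights subtract a local baseline (median intensity 0.02–0.03 ppm
  to either side of the annotated shift); an empty search window reports
  an absent peak (`NA`), never 0. On an isolated Lorentzian the flanking
  bands sit on the line's own tail, ≈ 1.4% of apex height — the tests use
  the analytic tail as the oracle rather than pretending the bias away.
* Zero-variance columns under auto/pareto scaling are dropped with a
  warning; requesting more LVs than the rank supports truncates with a
  warning; a CV training fold that loses a class is a stratification
  error.
* Unique-metabolite counting applies documented collapsing rules (strip
  parenthetical qualifiers and trailing "-like"/"-related"; drop
  unassigned; exclude composite "and/or" or slash-joined candidates as
  ambiguous). On the bundled 72-row polar table these rules yield 36
  unique names; published tallies that count composites differently can
  legitimately differ, and the function reports its own count rather than
  forcing agreement.

## 8. Problem sizes used in the automated studies

The test and acceptance studies run at reduced but representative sizes,
chosen as a deliberate compromise between Monte Carlo resolution and a
test suite that a maintainer will actually run: 4096–16384-point grids
(0.7–2.8 × 10⁻³ ppm spacing), SPA at 400 iterations for calibration/power
studies (≈ 60–70 inclusions per variable across 50 variables), 20
replicate cohorts per study, and MCCV at 10–100 repetitions inside
pipeline smoke tests. The package defaults (32k grid, 1000 SPA
iterations, 500 MCCV repetitions) are what an analysis of a real cohort
should use.

One calibration detail is worth recording: the permuted-label null study
uses *balanced* cohorts (18/18). With the real 23/14 imbalance, an
empirical-prior discriminant converges on the majority rule, whose null
error is the minority fraction (≈ 0.38), not 0.5; a symmetric null is the
meaningful calibration target for a chance-level band centred on 0.5.

## 9. Known limitations

* The full-resolution arm interpolates re-referenced spectra onto a common
  grid; no peak alignment (e.g. icoshift-style) is attempted.
* The lipid system estimates four global indices; molecular-species
  lipidomics, EPA/arachidonate-specific estimation and phospholipid-class
  quantification are beyond ¹H index resolution and out of scope.
* Pathway over-representation analysis depends on an external pathway
  database; the pipeline exports annotated metabolite names for use in
  external ORA tools instead of re-implementing one.
* The package never emulates cohort attrition (e.g. a validation run on
  n = 34 of 37 samples); it always reports the n actually used.
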