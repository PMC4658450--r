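---
title: "Methods: linking DOM optical properties to molecular formulae"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking DOM optical properties to molecular formulae}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions, and numerical choices
behind `domlink`. The package links two views of dissolved organic matter
(DOM): bulk optical measurements (CDOM absorbance, fluorescence EEMs) and
molecule-resolved FTICR-MS peak intensities, joined by per-formula Spearman
rank screening.

# Formula chemistry

A molecular formula is a vector of CHNOSP counts. Derived quantities:

* **Monoisotopic mass**: sum of counts times the IUPAC monoisotopic atomic
  masses (¹²C, ¹H, ¹⁴N, ¹⁶O, ³²S, ³¹P). Ion masses assume singly charged
  [M−H]⁻ (negative-mode ESI), neutral mass minus the proton mass
  1.00727645 Da.
* **AI-mod**: (1 + C − 0.5·O − S − 0.5·H)/(C − 0.5·O − N − S − P). Half the
  oxygen is discounted as carboxyl. A negative numerator or non-positive
  denominator clamps the index to 0; this is the usual convention for
  saturated or heteroatom-dominated formulae whose aromaticity is zero by
  construction, and it keeps the index total on [0, ∞). The original (full
  oxygen) aromaticity index and its later erratum variant are deliberately
  *not* implemented: one form, stated here, is used everywhere.
* **DBE** = 1 + C − H/2 + N/2 + P/2.
* **Compound classes** are assigned by a fixed precedence: sugars
  (O/C ≥ 0.9) first, then condensed aromatics (AI-mod ≥ 0.67), polyphenols
  (0.5 ≤ AI-mod < 0.67), saturated fatty acids (H/C ≥ 2), peptides
  (1.5 ≤ H/C < 2, N > 0), unsaturated aliphatics (same band, N = 0), highly
  unsaturated (AI-mod < 0.5, H/C < 1.5), and `other` for anything left. The
  precedence makes overlapping conditions (e.g. a high-O/C formula with low
  AI-mod) resolve deterministically; `other` is reported separately and
  never merged into a named class. The boundary conventions (≥ 0.67,
  N > 0, H/C ≥ 2, O/C ≥ 0.9) are the standard readings of these class
  definitions.

# Absorbance indices

Spectra are decadic absorbance on a wavelength grid with a known path
length (default 0.01 m). The Napierian absorption coefficient is
a(λ) = ln(10)·A(λ)/L (m⁻¹), with linear interpolation for off-grid
wavelengths (grids are 1 nm or finer; higher-order interpolation is
immaterial).

**SUVA254** divides the *decadic* coefficient at 254 nm by DOC
(mg-C L⁻¹) — the Weishaar convention — while CDOM work usually reports
*Napierian* a254. Both conventions are always emitted
(`suva254`, `suva254_napierian`), and `run_config(suva_variant=)` selects
which one the screen uses (default decadic). Iron corrections are out of
scope.

**Spectral slopes** are ordinary least squares of ln a(λ) on λ over
275–295 nm and 350–400 nm, sign-flipped so steeper decay gives a larger
positive S (nm⁻¹); the slope ratio SR = S275−295/S350−400. The log-then-OLS
estimator is used (not a nonlinear exponential fit). Non-positive
absorbance inside a window is an error that names the offending
wavelengths; a zero denominator slope makes SR a propagating missing value
rather than an exception, so batch runs continue.

# EEM processing and fluorescence indices

EEMs are excitation × emission intensity matrices with an explicit logical
mask; masked cells carry no meaning. Processing order: blank subtraction
(cellwise, floored at zero), inner-filter correction, scatter excision,
optional quinine-sulfate scaling (a single multiplicative factor, default 1,
because an instrument calibration is an input, not something the package can
reproduce).

* **Inner-filter correction** uses the absorbance-based (ABA) factor
  10^((A_ex + A_em)/2) with A the decadic absorbance per cm. ABA is the
  standard companion to a 1-cm cell. Cells with A_ex + A_em > 3 are
  corrected but flagged with a warning — the correction is unreliable at
  that opacity.
* **Scatter excision** masks |λem − λex| ≤ 15 nm (first order) and
  |λem − 2·λex| ≤ 15 nm (second order) by default. Excised cells are left
  missing rather than interpolated: interpolation would fabricate exactly
  the trilinear structure PARAFAC is supposed to find.
* **FI** = I(370, 470)/I(370, 520), emission linearly interpolated onto
  470/520 on the 2-nm grid; the excitation row must be within 2.5 nm of
  370 nm. **Freshness** = I(310, 380)/max I(310, 420–435). **HIX** uses
  trapezoidal areas H (435–480 nm) and L (300–345 nm) on a low-excitation
  row: the bounded form H/(H+L) ∈ [0, 1] and the ratio form H/L are both
  always computed. The classical definition reads the λex = 254 nm row; on
  grids starting at 260 nm the lowest available row is used and recorded in
  the output. Reported HIX values in the field literature often exceed 1,
  which is only possible in the ratio form; `run_config(hix_variant=)`
  therefore defaults to `"zsolnay"` (the ratio) for screening, with the
  bounded variant one flag away. The package takes no position on which
  variant any particular historical dataset used; it reports both.

# PARAFAC

The sample × excitation × emission tensor is assembled on a *fitting grid*:
emission trimmed to 300–600 nm and thinned to 4 nm. Two reasons. First,
the acquisition scheme scans emission only from λex+10 to λex+250 nm, so on
the full union grid more than half of each sample's cells were never
scanned; the trimmed range keeps per-sample missingness below 50%. Second,
fluorophore emission bands are 40–60 nm wide, so a 4-nm grid loses nothing
while conditioning the fit. Each sample slab is normalized to unit maximum
before fitting (factors retained), and the fitted spectral loadings are
afterwards projected onto the *non-normalized* EEMs by per-sample
nonnegative least squares, so scores are in original intensity units.
Within-sample score fractions (summing to 1) are what the screen uses.

## Solver

The fit minimizes the observed-cell residual sum of squares of the
trilinear model with nonnegativity in all three modes (fluorescence physics
admits no negative spectra or concentrations). Missing cells carry zero
weight — they are excluded, not imputed. Model-based imputation (EM) was
rejected because poorly observed regions then reinforce their own
predictions. The kernel (compiled, RcppArmadillo) is a weighted HALS:
each component column of each mode is updated by its exact entrywise
minimizer, with the residual maintained incrementally.

Two complications arise from the ragged scan and are handled explicitly:

* **Structural unidentifiability.** A loading cell whose wavelength is
  observed only where its component carries essentially no signal has
  near-zero design energy: any value fits the observed data equally well,
  and unregularized least squares parks arbitrary noise-driven mass there.
  An *identifiability ridge* — per component, a fraction `ridge_rel`
  (default 1e-4) of the maximum observed design energy in that mode — damps
  such cells toward zero while leaving well-observed cells essentially
  untouched.
* **Monotonicity of the recorded fit.** Removing already-accumulated
  unidentifiable mass can raise the SSE microscopically, so damping and a
  strictly non-increasing SSE cannot coexist in a single pass. The fit
  therefore runs in two stages: an exploratory stage (multi-start burn-in of
  `n_starts` random initializations for `burnin` sweeps, best start refined
  with plain ridge updates and SSE-guarded line-search extrapolation —
  extrapolated iterates are accepted only when they lower the SSE), and a
  recorded stage of up to `polish` *projected-ridge* sweeps starting from
  the exploratory optimum: each entry's ridge candidate is clamped to the
  interval around the unpenalized minimizer where the SSE does not
  increase. Starting from a damped solution, unidentifiable cells stay at
  zero, and every recorded sweep is non-increasing in SSE by construction.
  The reported `sse_history` is the recorded stage; the fit is bit-for-bit
  reproducible given `(seed, n_starts, tol)`.

Defaults: `tol = 1e-8` (relative SSE change), `max_iter = 2500`,
`n_starts = 10`, `burnin = 50`, `polish = 150`. The pipeline profile in
`run_config()` uses fewer starts and iterations because the cohort fit is
re-run downstream of any parameter change; the vignette's own runs and the
verification suite use `n_starts = 8`, `max_iter = 500`, `tol = 1e-8`.

Components are ordered by decreasing total score — their proportional
contribution to total fluorescence — and spectral loadings are scaled to
unit maximum with the scale absorbed into scores.

## Validation

Split-half validation randomly partitions samples into two halves, fits
each independently, matches components greedily by the smaller of the
excitation- and emission-mode Tucker congruences (cosine similarity), and
passes when all matched congruences reach 0.95 — a conventional threshold;
no published value is being reproduced by it. Core consistency
(CORCONDIA) is computed and reported but is deliberately not a gate:
validation is by split-half only.

# FTICR pipeline

Peaks with S/N > 5 are assigned CHNOSP formulae by exhaustive enumeration
within chemical bounds: C 1–60, H 1–120, N 0–4, O 0–40, S 0–2, P 0–1;
0.3 ≤ H/C ≤ 2.5; O/C ≤ 1.2; integer DBE in [0, 40] (the even-electron
parity rule for [M−H]⁻); mass window 150–750 Da; tolerance 0.2 ppm. All
bounds are configuration. The production assigner queries a sorted,
session-cached database of every admissible formula by binary search; a
deliberately naive brute-force enumerator (`assign_formula_bruteforce`)
implements the same contract by scanning the full element grid and serves
as its cross-check. When several candidates fall inside the tolerance the
smallest |ppm error| wins, ties broken by fewest heteroatoms, and the peak
is flagged ambiguous (kept, not dropped; downstream uses the winner only).

**DR/SDL standardization.** Each sample's dynamic range is the mean of its
top min(500, n) intensities over the mean of its 10 lowest. The cohort
minimum DR sets each sample's standardized detection limit
SDL = top-500 mean / min DR. Rows of the matrix are the union of assigned
formulae; a formula undetected in a sample — or detected below that
sample's SDL — is *set to the SDL*, not to zero or missing. The fill rule
is extended from "peaks below the SDL" to formulae absent from a sample
because the stated purpose of the SDL is to prevent false negatives across
samples; this materially changes correlation behaviour (rows become
constant when a formula is seen in only a few samples, and constant rows
are excluded from screening), which is why it is called out here. After
filling, every cell is ≥ its sample's SDL by construction, and each column
is normalized to unit total.

# Association screen

Spearman's rho uses average ranks for ties (Pearson on ranks). Two-sided
p-values: exact enumeration of all n! orderings for n ≤ 9, the
t-approximation t = ρ√((n−2)/(1−ρ²)) otherwise — at the design size n = 57
the approximation is standard, and its empirical size is checked by the
test suite's null simulation. Pairs involving a constant vector (typically
all-SDL rows) are reported missing and never significant. Significance is
raw two-sided p < 0.01 with a sign filter — the screen deliberately applies
no multiple-testing correction, reproducing the conventional 99%-confidence
screen; a Benjamini–Hochberg q-value column is emitted alongside as a
clearly-marked extension that no summary consumes. Whether historical
screens used one- or two-sided tests at p < 0.01 is usually unstated;
two-sided with a sign filter is the conservative implementation.

Class summaries count the significant set per property within each
category. Heteroatom groups are membership-based — "CHON" means contains
nitrogen whatever the S/P content — so CHO-only plus contains-N/S/P
reconciles exactly to the total; both count-percent and intensity-weighted
percent of each category are always emitted because published tables are
ambiguous about which they print. Shared-formula matrices count pairwise
intersections of significant sets; distribution profiles bin ion mass
(50 Da), H/C (0.1), and AI-mod (0.05) with both counts and intensity
weights; van Krevelen exports are tidy (O/C, H/C, class, stats) tables for
any plotting layer.

# Synthetic cohort generator

The generator emulates the study structure end to end so the pipeline can
be verified against a known truth: 57 samples; 4 trilinear components with
Gaussian excitation/emission bumps placed near the reported component
maxima (C1 ex 260/310, em 425; C2 ex 260/370, em 505; C3 ex 260/300,
em 375; C4 ex 275, em 320); log-normal scores with a planted abundance
ordering; EEMs = trilinear sum + first/second-order Rayleigh ridges +
Gaussian noise at 1% of each sample's maximum; inner-filter attenuation
consistent with each sample's absorbance spectrum; near-zero blanks.
Absorbance is piecewise log-linear with planted slopes drawn from the
reported field envelopes (S275−295 0.016–0.034 nm⁻¹, S350−400
0.008–0.030 nm⁻¹, Napierian a254 10–204 m⁻¹ log-uniform, DOC clipped to
3.3–20.4 mg-C L⁻¹) — envelopes are *plausibility calibration targets*, not
correctness assertions. The formula library (default 3000) is drawn from
the assignable CHNOSP database with class weights near reported DOM
composition; intensities are log-normal; planted formulae are tied to
drivers (C1–C4 fractions, SUVA254, FI by default) through Gaussian copulas.
Because Spearman correlation is copula-determined, planting at latent
Pearson r = 2·sin(π·ρ/6) gives population Spearman exactly ρ regardless of
the log-normal marginals. Exact [M−H]⁻ masses are perturbed by ≤ 0.1 ppm;
a known fraction of peaks receives S/N ≤ 5 so the read-time filter bites;
unassignable noise peaks exercise the union/fill machinery.

Calibration notes. The component widths and score separations were set so
the derived indices vary measurably across samples, as the field data's
printed envelopes require — most visibly FI: with Gaussian components at
the reported peak positions, a narrow C1 excitation band leaves FI almost
constant (no real cohort in which over a thousand formulae correlate with
FI could look like that), so C1's 310-nm band width is 40 nm and abundance
meanlogs are log(1.25, 0.6, 0.45, 0.3). The *level* of FI still sits
slightly below typical field values — idealized symmetric Gaussians with
these peak positions compress the 470/520 ratio — while its across-sample
spread, which is what rank screening uses, is realistic. What the generator
does **not** emulate: instrument physics (detector saturation, Raman
scatter, wavelength-dependent bias), seasonal/site covariance, ionization
suppression, isotopologues, and multiply charged species. Passing the
closed-loop tests therefore demonstrates that the pipeline recovers truth
under idealized trilinear + copula structure, not that any particular field
interpretation is correct.

# Verification sizes

The test suite and `scripts/acceptance.R` run at these problem sizes:
oracle agreement on 200 masses and round-trip on 1000 formulae at 0.2 ppm;
PARAFAC recovery and split-half over 20 generator seeds at the full cohort
size (57 samples, 1% noise), with fit protocol `n_starts = 8`,
`burnin = 50`, `max_iter = 500`, `tol = 1e-8`; screen calibration over 10⁵
null pairs and 500 planted ρ = 0.6 links at n = 57; one full
generate → process → screen closed loop. These sizes are the package's
validation design; the generator itself always defaults to the full study
conditions.

# Known limitations

* The PARAFAC ridge is a bias–variance trade: loading cells with modest
  (not near-zero) design energy are shrunk very slightly. At the default
  1e-4 the effect is far below the split-half congruence threshold.
* Formula assignment trusts the winner under the fewest-heteroatoms tie
  break; at 0.2 ppm a small percentage of masses are genuinely ambiguous
  and are only flagged, not resolved.
* The SDL fill creates tied ranks by design; heavily filled rows lose
  power, and fully filled rows are excluded from screening.
* The exact-p path enumerates n! orderings and is only used for n ≤ 9.
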