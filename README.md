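# domlink

Linking the optical properties of dissolved organic matter (DOM) to
ultrahigh-resolution mass-spectrometry molecular formulae.

## The problem

Absorbance and fluorescence measurements are fast, cheap proxies for DOM
composition: SUVA254 tracks aromaticity, spectral slopes track molecular
weight, EEM-PARAFAC components separate humic-like from protein-like
fluorophores. FTICR-MS, in contrast, resolves DOM into thousands of exact
masses that can be assigned CHNOSP molecular formulae. `domlink` implements
the statistical bridge between the two views: for every assigned formula, a
Spearman rank correlation between its (standardized, normalized) signal
intensity across samples and every optical property, screened at the 99%
confidence level. The formulae that track an optical index — summarized by
elemental group, stoichiometric compound class, van Krevelen position, and
mass / H:C / AI-mod distributions — describe the molecular families that the
easy-to-measure optics actually see.

The package is organised as an analysis workflow (`analysis/01…05`) over a
fully tested R package, and ships a synthetic-cohort generator with a
machine-readable ground-truth manifest, so every stage of the pipeline is
verifiable without access to field data.

## What is implemented

* **Formula chemistry** — monoisotopic masses, DBE, the modified aromaticity
  index AI-mod = (1 + C − 0.5·O − S − 0.5·H)/(C − 0.5·O − N − S − P), and the
  stoichiometric compound-class partition (black carbon AI-mod ≥ 0.67,
  polyphenols 0.5 ≤ AI-mod < 0.67, highly unsaturated, unsaturated
  aliphatics, saturated fatty acids, sugars, peptides).
* **Absorbance indices** — Napierian/decadic coefficients, SUVA254 (Weishaar
  convention, with the Napierian variant also emitted), spectral slopes
  S275−295 and S350−400 from log-linear regression, and their ratio SR.
* **EEM hygiene and fluorescence indices** — blank subtraction,
  absorbance-based inner-filter correction, first/second-order
  Rayleigh-scatter excision (excised cells stay missing), FI, freshness, and
  HIX in both the bounded and ratio formulations.
* **PARAFAC** — nonnegative trilinear decomposition of the
  sample × excitation × emission tensor by weighted HALS (compiled,
  RcppArmadillo), with missing-cell weighting, an identifiability ridge for
  the ragged emission scan, multi-start initialization, a recorded fit whose
  SSE trajectory is non-increasing by construction, split-half validation by
  Tucker congruence, core consistency, and projection of scores onto the
  non-normalized EEMs.
* **FTICR pipeline** — CHNOSP formula assignment at 0.2 ppm ([M−H]⁻, S/N > 5)
  against an enumerated formula database, with a brute-force reference
  enumerator for cross-checking; dynamic-range (DR) and standardized
  detection limit (SDL) intensity standardization; column-stochastic
  normalization.
* **Association screen** — Spearman rho with average-rank ties; exact
  permutation p for n ≤ 9, t-approximation otherwise; class summaries,
  shared-formula matrices, distribution profiles, van Krevelen exports.
* **Synthetic cohort generator** — 57 samples, 4 fluorescent components, the
  instrument grids, exponential absorbance with planted slopes, ~3000
  formulae with Gaussian-copula links to optical drivers at stated
  population Spearman rho, and a truth manifest sufficient to recompute
  every expected output.

## Worked example

```r
library(domlink)

cohort <- generate_cohort(generator_config(), seed = 7)   # synthetic study
res <- run_all(cohort, run_config(parafac_n_starts = 8,
                                  parafac_max_iter = 500,
                                  parafac_tol = 1e-8))
res$model
#> PARAFAC model: 4 components, 57 samples, EV 0.9994, 150 iterations (...)
res$split_half$congruence
#> 0.999 0.977 1.000 0.965        # all >= 0.95: the 4-component model validates
colMeans(res$fractions)
#> 0.465 0.226 0.197 0.112        # share of total fluorescence, C1 > ... > C4
res$shared_matrix["c3", "c4"]
#> 31                             # formulae tracking both C3 and C4
```

The explained variance says the trilinear model captures >99.9% of the
observed fluorescence; the split-half congruences validate four components;
the component fractions decrease from C1 to C4 (the naming convention); and
the shared-formula count recovers the 30 formulae the generator planted
jointly on C3 and C4 (one extra formula is a chance association at
p < 0.01). The same drivers screened against the ~3000-formula matrix
recover 100% of the planted links with population rho ≥ 0.7 at a ~1%
false-positive rate among unplanted formula–property pairs.

The scripts in `analysis/` run the same pipeline stage by stage
(`01_simulate_cohort.R` → `05_association_screen.R`), printing a narrative
summary and writing all tables under `results/`.

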