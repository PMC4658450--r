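#!/usr/bin/env Rscript
# Stage 2: CDOM absorbance and fluorescence indices.
#
# Computes, per sample: Napierian and decadic a254, SUVA254 (both
# conventions), spectral slopes S275-295 and S350-400 with their ratio SR,
# and — after blank subtraction, inner-filter correction and Rayleigh-scatter
# excision — FI, the freshness index, and HIX in both the bounded (Ohno) and
# ratio (Zsolnay) formulations.

library(domlink)

cohort <- read_cohort("results/cohort")
ids <- cohort$samples$sample_id

abs_idx <- do.call(rbind, lapply(seq_along(ids), function(i) {
  cbind(sample_id = ids[i],
        absorbance_indices(cohort$absorbance[[i]],
                           cohort$samples$doc_mg_per_l[i]))
}))

fl_idx <- do.call(rbind, lapply(seq_along(ids), function(i) {
  x <- blank_subtract(cohort$eems[[i]], cohort$blanks[[i]])
  x <- inner_filter_correct(x, cohort$absorbance[[i]])
  x <- excise_scatter(x)
  cbind(sample_id = ids[i], fluorescence_indices(x))
}))

dir.create("results", showWarnings = FALSE)
write.csv(abs_idx, "results/absorbance_indices.csv", row.names = FALSE)
write.csv(fl_idx, "results/fluorescence_indices.csv", row.names = FALSE)

rng <- function(v) paste(signif(range(v, na.rm = TRUE), 3), collapse = " - ")
cat("index ranges across", length(ids), "samples:\n")
cat("  a254 (Napierian, 1/m):", rng(abs_idx$a254), "\n")
cat("  SUVA254 (L/mg-C/m):   ", rng(abs_idx$suva254), "\n")
cat("  S275-295 (1/nm):      ", rng(abs_idx$s275_295), "\n")
cat("  S350-400 (1/nm):      ", rng(abs_idx$s350_400), "\n")
cat("  SR:                   ", rng(abs_idx$s_r), "\n")
cat("  FI:                   ", rng(fl_idx$fi), "\n")
cat("  freshness:            ", rng(fl_idx$freshness), "\n")
cat("  HIX (ratio form):     ", rng(fl_idx$hix_zsolnay), "\n")
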