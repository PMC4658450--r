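#!/usr/bin/env Rscript
# Stage 4: FTICR-MS formula matrix.
#
# Filters each peak list at S/N > 5, assigns CHNOSP molecular formulae to
# [M-H]- masses at 0.2 ppm, standardizes detection limits across samples by
# the dynamic-range / SDL procedure (cells below a sample's SDL, or absent
# from it, are set to that sample's SDL), and normalizes each sample column
# to unit total intensity. Annotations carry mass, O/C, H/C, DBE, AI-mod and
# the stoichiometric compound class of every formula.

library(domlink)

cohort <- read_cohort("results/cohort")
pm <- peak_matrix(cohort$peaklists, cohort$samples$sample_id)
print(pm)

cat("\nassignment summary (medians across samples):\n")
print(vapply(pm$assignment_counts[-1], stats::median, numeric(1)))

ann <- pm$annotations
cat("\nformula categorization (all formulae, cohort union):\n")
groups <- c(total = nrow(ann), cho_only = sum(ann$cho_only),
            chon = sum(ann$has_n), chos = sum(ann$has_s),
            chop = sum(ann$has_p),
            contains_nsp = sum(ann$has_n | ann$has_s | ann$has_p))
print(groups)
print(table(ann$compound_class))
cat("mean ion m/z:", round(mean(ann$ion_mz), 1), "Da\n")

dir.create("results/matrix", showWarnings = FALSE, recursive = TRUE)
write.csv(ann, "results/matrix/annotations.csv", row.names = FALSE)
write.csv(data.frame(formula = rownames(pm$intensities), pm$intensities,
                     check.names = FALSE),
          "results/matrix/intensities.csv", row.names = FALSE)
write.csv(data.frame(formula = rownames(pm$normalized), pm$normalized,
                     check.names = FALSE),
          "results/matrix/normalized.csv", row.names = FALSE)
write.csv(data.frame(sample_id = pm$samples, dr = pm$dr, sdl = pm$sdl),
          "results/matrix/dr_sdl.csv", row.names = FALSE)
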