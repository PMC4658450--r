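#!/usr/bin/env Rscript
# Stage 3: PARAFAC decomposition of the EEM tensor.
#
# Stacks the processed EEMs into a sample x excitation x emission tensor on
# the validated fitting range (emission 300-600 nm, thinned to 4 nm),
# normalizes each sample to unit maximum, fits the 4-component nonnegative
# trilinear model, validates it by split-half Tucker congruence, and projects
# the spectral loadings back onto the non-normalized EEMs so scores are in
# original intensity units. Components are numbered by decreasing share of
# total fluorescence.

library(domlink)

cohort <- read_cohort("results/cohort")
ids <- cohort$samples$sample_id

processed <- lapply(seq_along(ids), function(i) {
  x <- blank_subtract(cohort$eems[[i]], cohort$blanks[[i]])
  x <- inner_filter_correct(x, cohort$absorbance[[i]])
  excise_scatter(x)
})

tens <- eem_tensor(processed, ids)
norm <- normalize_for_fit(tens)
model <- fit_parafac(norm$tensor, k = 4, tol = 1e-8, max_iter = 500,
                     n_starts = 8, seed = 7)
print(model)
cat("core consistency:", round(core_consistency(model, norm$tensor), 1), "%\n")

sh <- split_half_validate(norm$tensor, 4, seed = 7, n_starts = 10,
                          max_iter = 400, burnin = 30)
cat("split-half congruences:", round(sh$congruence, 4),
    if (sh$pass) "(validated)" else "(NOT validated)", "\n")

scores <- project_scores(model, tens)
fractions <- normalize_scores(scores)
cat("mean component fractions:", round(colMeans(fractions), 3), "\n")
cat("excitation maxima (nm):",
    model$excitation[apply(model$ex_loadings, 2, which.max)], "\n")
cat("emission maxima (nm):",
    model$emission[apply(model$em_loadings, 2, which.max)], "\n")

write_parafac_model(model, "results/model")
write.csv(data.frame(sample_id = rownames(scores), scores),
          "results/parafac_scores.csv", row.names = FALSE)
write.csv(data.frame(sample_id = rownames(fractions), fractions),
          "results/parafac_fractions.csv", row.names = FALSE)
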