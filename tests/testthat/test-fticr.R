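test_that("known ion masses assign to the right formulae", {
  db <- build_formula_db()
  mz_palmitate <- monoisotopic_mass(molecular_formula(16, 32, o = 2)) - PROTON_MASS
  res <- assign_formulas(mz_palmitate, db = db)
  expect_true(res$assigned)
  expect_identical(res$formula, "C16H32O2")
  expect_lt(abs(res$error_ppm), 0.2)
  # an empty candidate set stays unassigned
  tight <- assignment_config(c_bounds = c(5L, 60L), h_bounds = c(5L, 120L))
  res2 <- assign_formulas(155.000000, tight)
  expect_false(res2$assigned)
  expect_identical(res2$n_candidates, 0L)
  # degenerate tolerance is a configuration error
  expect_error(assignment_config(tolerance_ppm = 0), "positive")
  # out-of-range masses are skipped, not errors
  res3 <- assign_formulas(900, db = db)
  expect_false(res3$assigned)
  expect_false(res3$in_range)
})

test_that("optimized assigner agrees with the brute-force enumerator", {
  db <- build_formula_db()
  set.seed(15)
  mz <- c(runif(10, 150, 750),
          db$ion_mz[sample(nrow(db), 10)] * (1 + runif(10, -0.1, 0.1) * 1e-6))
  opt <- assign_formulas(mz, db = db)
  bf <- do.call(rbind, lapply(mz, assign_formula_bruteforce))
  expect_identical(opt$assigned, bf$assigned)
  expect_identical(opt$formula, bf$formula)
})

test_that("formulae round-trip through their exact ion masses", {
  db <- build_formula_db()
  set.seed(16)
  idx <- sample(nrow(db), 200)
  res <- assign_formulas(db$ion_mz[idx], db = db)
  ok <- res$assigned & res$formula == format_formula(db[idx, ])
  expect_gte(mean(ok), 0.98)
})

test_that("dynamic range is top-500 mean over lowest-10 mean", {
  set.seed(17)
  v <- c(runif(500, 4000, 6000), runif(10, 40, 60))
  expected <- mean(sort(v, decreasing = TRUE)[1:500]) / mean(sort(v)[1:10])
  expect_equal(dynamic_range(v), expected)
  expect_equal(dynamic_range(rep(7, 50)), 1)
  expect_error(dynamic_range(1:9), "at least 10")
})

test_that("SDL standardization fills below-limit and missing cells", {
  # sample A: DR = 100, sample B: DR = 50 -> DR_min = 50
  pa <- c(rep(5000, 500), rep(50, 10))
  pb <- c(rep(2000, 500), rep(40, 10))
  fa <- c(F1 = 5000, F2 = 200)          # F2 below SDL_A = 5000/50 = 100
  fb <- c(F1 = 2000)                    # F2 undetected in B
  std <- sdl_standardize(list(A = fa, B = fb), list(pa, pb))
  expect_equal(unname(std$dr), c(100, 50))
  expect_equal(unname(std$sdl), c(100, 40))
  expect_equal(std$intensities["F1", ], c(A = 5000, B = 2000))
  expect_equal(std$intensities["F2", "A"], 200)      # detected above SDL
  expect_equal(std$intensities["F2", "B"], 40)       # filled with SDL_B
  expect_gte(min(sweep(std$intensities, 2, std$sdl, `-`)), 0)
  # identical samples leave detected intensities untouched
  std2 <- sdl_standardize(list(A = fa, B = fa), list(pa, pa))
  expect_equal(std2$intensities["F1", ], c(A = 5000, B = 5000))
  expect_error(sdl_standardize(list(A = fa), list(pa)), "at least 2")
})

test_that("column normalization is column-stochastic and drops zero columns", {
  m <- cbind(A = c(2, 3, 5), B = c(1, 0, 0), C = c(0, 0, 0))
  rownames(m) <- paste0("F", 1:3)
  expect_message(nm <- normalize_columns(m), "zero-total")
  expect_equal(unname(colSums(nm)), c(1, 1))
  expect_equal(unname(nm[, "A"]), c(0.2, 0.3, 0.5))
  expect_equal(unname(nm[, "B"]), c(1, 0, 0))
})

test_that("peak matrix reproduces the generator's formula library", {
  # exact masses: the winner rule must reproduce the library perfectly
  cfg <- small_generator_config(n_noise_peaks = 0, low_snr_prob = 0,
                                mz_jitter_ppm = 0)
  coh <- generate_cohort(cfg, seed = 23)
  pm <- peak_matrix(coh$peaklists, coh$samples$sample_id)
  lib <- coh$manifest$formulas
  expect_setequal(rownames(pm$intensities), lib$formula)
  # per-class counts match the manifest exactly
  got <- table(factor(pm$annotations$compound_class, COMPOUND_CLASSES))
  want <- table(factor(lib$compound_class, COMPOUND_CLASSES))
  expect_equal(as.integer(got), as.integer(want))
  # with sub-tolerance mass jitter a handful of near-degenerate masses may
  # swap winners; the library must still be recovered near-perfectly
  cfgj <- small_generator_config(n_noise_peaks = 0, low_snr_prob = 0,
                                 mz_jitter_ppm = 0.05)
  cohj <- generate_cohort(cfgj, seed = 23)
  pmj <- peak_matrix(cohj$peaklists, cohj$samples$sample_id)
  shared <- intersect(rownames(pmj$intensities), cohj$manifest$formulas$formula)
  expect_gte(length(shared) / nrow(cohj$manifest$formulas), 0.99)
  # every cell respects its sample's SDL and columns are normalized
  expect_gte(min(sweep(pm$intensities, 2, pm$sdl, `-`)), 0)
  expect_equal(unname(colSums(pm$normalized)), rep(1, length(pm$samples)),
               tolerance = 1e-9)
})

test_that("S/N filtering drops peaks at read time", {
  pl <- data.frame(mz = c(300.1, 300.2, 300.3), intensity = c(10, 20, 30),
                   snr = c(3, 5, 10))
  path <- tempfile(fileext = ".csv")
  utils::write.csv(pl, path, row.names = FALSE)
  back <- read_peaklist_csv(path)
  expect_identical(nrow(back), 3L)      # reading does not filter
  cfg <- assignment_config()
  expect_identical(sum(back$snr > cfg$snr_min), 1L)
})
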