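test_that("identical configuration and seed reproduce the cohort exactly", {
  cfg <- small_generator_config()
  c1 <- generate_cohort(cfg, seed = 31)
  c2 <- generate_cohort(cfg, seed = 31)
  expect_identical(c1$eems[[3]]$intensity, c2$eems[[3]]$intensity)
  expect_identical(c1$peaklists[[5]], c2$peaklists[[5]])
  expect_identical(c1$manifest$scores, c2$manifest$scores)
  c3 <- generate_cohort(cfg, seed = 32)
  expect_false(identical(c1$eems[[3]]$intensity, c3$eems[[3]]$intensity))
})

test_that("noiseless scatter-free cohorts reproduce manifest closed forms", {
  cfg <- small_generator_config(noise_level = 0, scatter_amplitude = 0,
                                blank_level = 0, n_formulae = 50,
                                n_noise_peaks = 0, low_snr_prob = 0,
                                plant_drivers = "c1", plant_rhos = 0.8,
                                n_overlap = 0)
  coh <- generate_cohort(cfg, seed = 33)
  proc <- process_eems(coh)
  ot <- coh$manifest$optics_true
  expect_equal(vapply(proc, fluorescence_index, numeric(1)), ot$fi,
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(vapply(proc, freshness_index, numeric(1)), ot$freshness,
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(vapply(proc, function(x) hix(x)$hix_zsolnay, numeric(1)),
               ot$hix, tolerance = 1e-9, ignore_attr = TRUE)
  a254 <- vapply(seq_along(proc), function(i) {
    napierian_coefficient(coh$absorbance[[i]], 254)
  }, numeric(1))
  expect_equal(a254, ot$a254, tolerance = 1e-9)
})

test_that("Gaussian-copula plants land near their population Spearman rho", {
  set.seed(34)
  n <- 57
  target <- 0.9
  r <- 2 * sin(pi * target / 6)
  rhos <- replicate(500, {
    d <- rnorm(n)
    z <- r * domlink:::.rank_latent(d) + sqrt(1 - r^2) * rnorm(n)
    stats::cor(d, qlnorm(pnorm(z), 16, 0.7), method = "spearman")
  })
  expect_lt(abs(mean(rhos) - target), 0.03)
  expect_gte(mean(abs(rhos - target) <= 0.15), 0.99)
})

test_that("manifests round-trip through JSON", {
  coh <- get_small_cohort()
  path <- tempfile(fileext = ".json")
  write_manifest(coh$manifest, path)
  back <- read_manifest(path)
  expect_equal(back$scores, coh$manifest$scores)
  expect_equal(back$ex_loadings, coh$manifest$ex_loadings, ignore_attr = TRUE)
  expect_equal(back$formulas$formula, coh$manifest$formulas$formula)
  expect_equal(back$formulas$planted_rho, coh$manifest$formulas$planted_rho)
  expect_equal(back$optics_true$fi, coh$manifest$optics_true$fi)
  expect_equal(back$seed, coh$manifest$seed, ignore_attr = TRUE)
})

test_that("cohorts round-trip through their on-disk file layout", {
  coh <- get_small_cohort()
  dir <- tempfile()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(back$samples$doc_mg_per_l, coh$samples$doc_mg_per_l)
  expect_equal(back$eems[[2]]$intensity, coh$eems[[2]]$intensity,
               tolerance = 1e-12)
  expect_identical(back$eems[[2]]$mask, coh$eems[[2]]$mask)
  expect_equal(back$peaklists[[4]]$mz, coh$peaklists[[4]]$mz, tolerance = 1e-12)
  expect_equal(back$manifest$scores, coh$manifest$scores)
})

test_that("expected outputs derive significant sets from power alone", {
  coh <- get_small_cohort()
  # n = 20 here, so use a threshold matched to the small cohort's power
  exp_out <- expected_outputs(coh$manifest, power_threshold = 0.9)
  lib <- coh$manifest$formulas
  # with no plants there is nothing to expect
  cfg0 <- small_generator_config(plant_drivers = character(0),
                                 plant_rhos = numeric(0), n_overlap = 0)
  coh0 <- generate_cohort(cfg0, seed = 35)
  exp0 <- expected_outputs(coh0$manifest)
  expect_identical(length(exp0$expected_positive), 0L)
  # strong plants are all expected; the sets match the planted table
  strong <- lib[!is.na(lib$planted_driver) & !lib$overlap_plant &
                  lib$planted_rho >= 0.7, ]
  for (d in unique(strong$planted_driver)) {
    expect_setequal(exp_out$expected_positive[[d]],
                    strong$formula[strong$planted_driver == d])
  }
  # class counts in the expected table match a direct tally
  cc <- exp_out$expected_class_counts
  d1 <- unique(strong$planted_driver)[1]
  tally <- table(factor(strong$compound_class[strong$planted_driver == d1],
                        COMPOUND_CLASSES))
  expect_equal(cc$n_expected[cc$driver == d1], as.integer(tally))
  expect_identical(length(exp_out$expected_overlap), 6L)
})

test_that("analytic screen power behaves sensibly", {
  expect_gt(spearman_power(0.9, 57), 0.9999)
  expect_gt(spearman_power(0.7, 57), 0.999)
  expect_lt(spearman_power(0.2, 20), 0.5)
  expect_equal(spearman_power(0.6, 57), spearman_power(-0.6, 57))
})
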