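test_that("blank subtraction differences, floors, and guards grids", {
  ex <- seq(300, 320, 5); em <- seq(320, 360, 4)
  s <- toy_eem(ex, em, function(a, b) 2 + 0 * a)
  b <- toy_eem(ex, em, function(a, b) 0.5 + 0 * a)
  d <- blank_subtract(s, b)
  expect_true(all(d$intensity[!d$mask] == 1.5))
  expect_identical(d$units_tag, "blank_subtracted")
  expect_true(all(blank_subtract(s, s)$intensity[!s$mask] == 0))
  big <- toy_eem(ex, em, function(a, b) 3 + 0 * a)
  expect_true(all(blank_subtract(s, big)$intensity[!s$mask] == 0))  # floor
  other <- toy_eem(ex, em + 2, function(a, b) 1 + 0 * a)
  expect_error(blank_subtract(s, other), "grids")
})

test_that("inner-filter correction applies the ABA factor", {
  ex <- c(300, 310); em <- c(400, 410)
  x <- toy_eem(ex, em, function(a, b) 1 + 0 * a)
  # flat decadic absorbance 0.1 per cm over a 1 cm cell
  sp <- absorbance_spectrum(250:800, rep(0.1, 551), 0.01)
  y <- inner_filter_correct(x, sp)
  expect_equal(y$intensity[1, 1], 10^0.1, tolerance = 1e-12)
  sp0 <- absorbance_spectrum(250:800, rep(0, 551), 0.01)
  expect_equal(inner_filter_correct(x, sp0)$intensity, x$intensity)
  narrow <- absorbance_spectrum(250:350, rep(0.1, 101), 0.01)
  expect_error(inner_filter_correct(x, narrow), "cover")
  opaque <- absorbance_spectrum(250:800, rep(1.6, 551), 0.01)
  expect_warning(inner_filter_correct(x, opaque), "unreliable")
})

test_that("inner-filter correction is monotone in absorbance", {
  set.seed(9)
  ex <- seq(260, 400, 20); em <- seq(300, 600, 25)
  x <- toy_eem(ex, em, function(a, b) exp(-((b - 450) / 80)^2) + 0 * a)
  a1 <- runif(551, 0, 0.5)
  a2 <- a1 + runif(551, 0, 0.2)
  y1 <- inner_filter_correct(x, absorbance_spectrum(250:800, a1, 0.01))
  y2 <- inner_filter_correct(x, absorbance_spectrum(250:800, a2, 0.01))
  expect_true(all(y2$intensity[!x$mask] >= y1$intensity[!x$mask]))
})

test_that("scatter excision masks the stated bands and is idempotent", {
  x <- toy_eem(300, seq(305, 315, 5), function(a, b) 1 + 0 * a)
  y <- excise_scatter(x, first_width = 10, second_width = 10)
  expect_identical(as.logical(y$mask), c(TRUE, TRUE, FALSE))  # 305, 310 masked
  expect_identical(attr(y, "n_excised"), 2L)
  x2 <- toy_eem(300, c(580, 600, 620), function(a, b) 1 + 0 * a)
  y2 <- excise_scatter(x2, 15, 15)
  expect_identical(as.logical(y2$mask), c(FALSE, TRUE, FALSE))  # |600 - 2*300| = 0
  y3 <- excise_scatter(y2, 15, 15)
  expect_identical(y3$mask, y2$mask)
  expect_identical(attr(y3, "n_excised"), 0L)
  x3 <- toy_eem(300, c(360, 400), function(a, b) 1 + 0 * a)
  expect_identical(sum(excise_scatter(x3, 1e-6, 1e-6)$mask), 0L)
  expect_error(excise_scatter(x3, 0, 5), "positive")
})

test_that("fluorescence index interpolates emission onto 470/520", {
  ex <- c(365, 370, 375)
  em <- c(469, 471, 519, 521)
  inten <- rbind(rep(1, 4), c(1.9, 2.1, 0.9, 1.1), rep(1, 4))
  x <- eem(ex, em, inten)
  expect_equal(fluorescence_index(x), 2.0, tolerance = 1e-12)
  eq <- eem(ex, em, matrix(3, 3, 4))
  expect_equal(fluorescence_index(eq), 1.0)
  zero <- eem(ex, em, matrix(0, 3, 4))
  expect_true(is.na(fluorescence_index(zero)))           # denominator 0
  far <- eem(c(340, 350), em, matrix(1, 2, 4))
  expect_true(is.na(fluorescence_index(far)))            # no ex 370 row
})

test_that("freshness index divides by the 420-435 window maximum", {
  ex <- c(305, 310)
  em <- c(380, 420, 428, 435)
  x <- eem(ex, em, rbind(rep(1, 4), c(10, 3, 5, 4)))
  expect_equal(freshness_index(x), 2.0)
  x2 <- eem(ex, em, rbind(rep(1, 4), c(5, 5, 4, 3)))
  expect_equal(freshness_index(x2), 1.0)
  x3 <- eem(ex, em, rbind(rep(1, 4), rep(0, 4)))
  expect_true(is.na(freshness_index(x3)))
})

test_that("HIX areas give both bounded and ratio formulations", {
  ex <- c(260, 300)
  em <- seq(290, 500, 1)
  # equal rectangular bands over the two windows
  v <- ifelse((em >= 300 & em <= 345) | (em >= 435 & em <= 480), 2, 0)
  x <- eem(ex, em, rbind(v, v))
  h <- hix(x)
  expect_equal(h$hix_ohno, 0.5, tolerance = 1e-6)
  expect_equal(h$hix_zsolnay, 1.0, tolerance = 1e-6)
  expect_identical(h$excitation_used, 260)
  vh <- ifelse(em >= 435 & em <= 480, 2, 0)
  hh <- hix(eem(ex, em, rbind(vh, vh)))
  expect_equal(hh$hix_ohno, 1.0)
  expect_true(is.na(hh$hix_zsolnay))
  h0 <- hix(eem(ex, em, matrix(0, 2, length(em))))
  expect_equal(h0$hix_ohno, 0)
  expect_equal(h0$hix_zsolnay, 0)
})

test_that("hix_ohno stays within [0, 1] on random EEMs", {
  set.seed(77)
  ex <- c(260, 280); em <- seq(290, 500, 10)
  ok <- replicate(1e4, {
    x <- eem(ex, em, matrix(rexp(2 * length(em)), 2))
    v <- hix(x)$hix_ohno
    v >= 0 && v <= 1
  })
  expect_true(all(ok))
})

test_that("indices after scatter excision stay close to scatter-free truth", {
  set.seed(31)
  cfg <- generator_config()
  ex <- cfg$ex_grid; em <- cfg$em_grid
  diffs <- replicate(500, {
    c1 <- outer(exp(-((ex - 330) / 40)^2), exp(-((em - 430) / 45)^2))
    c2 <- outer(exp(-((ex - 370) / 30)^2), exp(-((em - 505) / 50)^2))
    truthm <- runif(1, 0.5, 2) * c1 + runif(1, 0.2, 1) * c2
    d1 <- outer(ex, em, function(a, b) b - a)
    d2 <- outer(ex, em, function(a, b) b - 2 * a)
    scat <- 0.3 * max(truthm) * (exp(-d1^2 / 50) + 0.5 * exp(-d2^2 / 98))
    clean <- eem(ex, em, truthm)
    dirty <- excise_scatter(eem(ex, em, truthm + scat), 15, 15)
    abs(fluorescence_index(dirty) - fluorescence_index(clean)) /
      fluorescence_index(clean)
  })
  expect_false(anyNA(diffs))
  expect_true(all(diffs < 0.02))
})

test_that("EEM CSV round-trips exactly, including masked cells", {
  coh <- get_small_cohort()
  x <- excise_scatter(coh$eems[[1]])
  path <- tempfile(fileext = ".csv")
  write_eem_csv(x, path)
  back <- read_eem_csv(path)
  expect_equal(back$excitation, x$excitation)
  expect_equal(back$emission, x$emission)
  expect_identical(back$mask, x$mask)
  expect_equal(back$intensity[!x$mask], x$intensity[!x$mask], tolerance = 1e-12)
})
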