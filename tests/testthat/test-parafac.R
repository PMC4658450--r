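# Small synthetic tensors with known trilinear structure.
make_tensor <- function(ns = 12, k = 2, noise = 0, seed = 1,
                        nex = 12, nem = 20) {
  set.seed(seed)
  ex <- seq(260, 260 + 5 * (nex - 1), 5)
  em <- seq(320, 320 + 8 * (nem - 1), 8)
  B <- vapply(seq_len(k), function(r) {
    exp(-((ex - (280 + 30 * (r - 1))) / 18)^2)
  }, numeric(nex))
  C <- vapply(seq_len(k), function(r) {
    exp(-((em - (360 + 60 * (r - 1))) / 35)^2)
  }, numeric(nem))
  B <- sweep(B, 2, apply(B, 2, max), `/`)
  C <- sweep(C, 2, apply(C, 2, max), `/`)
  A <- matrix(rlnorm(ns * k, log(seq(2, 1, length.out = k))[col(matrix(0, ns, k))], 0.3), ns, k)
  eems <- lapply(seq_len(ns), function(i) {
    slab <- matrix(0, nex, nem)
    for (r in seq_len(k)) slab <- slab + A[i, r] * outer(B[, r], C[, r])
    slab <- slab + matrix(rnorm(nex * nem, 0, noise * max(slab)), nex, nem)
    eem(ex, em, slab)
  })
  list(tensor = eem_tensor(eems, paste0("S", seq_len(ns)),
                           em_range = range(em), em_step = 1),
       A = A, B = B, C = C)
}

test_that("a noiseless rank-1 tensor is recovered essentially exactly", {
  tt <- make_tensor(ns = 6, k = 1)
  fit <- fit_parafac(tt$tensor, 1, tol = 1e-12, max_iter = 300, n_starts = 2,
                     seed = 5)
  expect_gte(fit$explained_variance, 0.9999)
  expect_gte(tucker_congruence(fit$ex_loadings[, 1], tt$B[, 1]), 0.9999)
  expect_gte(tucker_congruence(fit$em_loadings[, 1], tt$C[, 1]), 0.9999)
})

test_that("component-count guards reject degenerate requests", {
  tt <- make_tensor(ns = 6, k = 1)
  expect_error(fit_parafac(tt$tensor, 0), "k must be")
  expect_error(fit_parafac(tt$tensor, 50), "exceeds")
})

test_that("per-sample normalization rescales to unit maximum and excludes zeros", {
  tt <- make_tensor(ns = 5, k = 2, seed = 3)
  t0 <- tt$tensor
  t0$values[2, , ] <- 0                      # an all-zero sample
  expect_message(norm <- normalize_for_fit(t0), "excluding")
  expect_identical(norm$excluded, "S2")
  mx <- apply(norm$tensor$values, 1, max)
  expect_equal(unname(mx), rep(1, 4))
  # already-unit slab keeps factor 1
  t1 <- norm$tensor
  n2 <- normalize_for_fit(t1)
  expect_equal(unname(n2$scale_factors), rep(1, 4))
})

test_that("the recorded SSE trajectory is non-increasing", {
  tt <- make_tensor(ns = 10, k = 2, noise = 0.02, seed = 7)
  fit <- fit_parafac(tt$tensor, 2, tol = 1e-10, max_iter = 300, n_starts = 3,
                     seed = 7)
  h <- fit$sse_history
  expect_true(all(diff(h) <= 1e-8 * pmax(h[-length(h)], 1e-300)))
  expect_true(fit$sse_monotone)
})

test_that("fits are bit-for-bit reproducible for a fixed seed", {
  tt <- make_tensor(ns = 8, k = 2, noise = 0.01, seed = 2)
  f1 <- fit_parafac(tt$tensor, 2, tol = 1e-9, max_iter = 200, n_starts = 3, seed = 42)
  f2 <- fit_parafac(tt$tensor, 2, tol = 1e-9, max_iter = 200, n_starts = 3, seed = 42)
  expect_identical(f1$scores, f2$scores)
  expect_identical(f1$ex_loadings, f2$ex_loadings)
  expect_identical(f1$sse_history, f2$sse_history)
})

test_that("permuting sample order permutes scores and leaves loadings stable", {
  tt <- make_tensor(ns = 10, k = 2, noise = 0.005, seed = 4)
  perm <- c(4, 1, 9, 2, 10, 3, 7, 5, 8, 6)
  tp <- tt$tensor
  tp$values <- tp$values[perm, , ]
  tp$mask <- tp$mask[perm, , ]
  tp$sample_ids <- tp$sample_ids[perm]
  f1 <- fit_parafac(tt$tensor, 2, tol = 1e-10, max_iter = 400, n_starts = 3, seed = 8)
  f2 <- fit_parafac(tp, 2, tol = 1e-10, max_iter = 400, n_starts = 3, seed = 8)
  m <- domlink:::.match_components(f1$ex_loadings, f1$em_loadings,
                                   f2$ex_loadings, f2$em_loadings)
  expect_true(all(m$congruence > 0.999))
  s2 <- f2$scores[, m$comp_b[order(m$comp_a)], drop = FALSE]
  expect_true(all(abs(f1$scores[perm, ] - s2) < 1e-3 * max(f1$scores)))
})

test_that("projection reproduces fit scores and handles constructed samples", {
  tt <- make_tensor(ns = 8, k = 2, seed = 6)
  norm <- normalize_for_fit(tt$tensor)
  # full tensor, no unidentifiable cells: fit without the ridge so the
  # NNLS projection is an exact inverse of the fit
  fit <- fit_parafac(norm$tensor, 2, tol = 1e-12, max_iter = 800, n_starts = 3,
                     seed = 3, ridge_rel = 0)
  # projecting the non-normalized tensor recovers fit scores x scale factors
  sc <- project_scores(fit, tt$tensor)
  expected <- fit$scores * norm$scale_factors
  expect_equal(unname(sc), unname(expected), tolerance = 1e-5)
  # a pure single-component sample picks up only that component
  single <- tt$tensor
  slab <- 3 * outer(fit$ex_loadings[, 1], fit$em_loadings[, 1])
  single$values[1, , ] <- slab
  single$mask[1, , ] <- FALSE
  sc1 <- project_scores(fit, single)[1, ]
  expect_equal(unname(sc1[2]), 0, tolerance = 1e-8)
  expect_equal(unname(sc1[1]), 3, tolerance = 1e-6)
  # an all-zero sample gets zero scores
  zero <- tt$tensor
  zero$values[2, , ] <- 0
  expect_equal(unname(project_scores(fit, zero)[2, ]), c(0, 0))
})

test_that("score normalization yields per-sample fractions", {
  s <- rbind(c(2, 1, 1, 0), c(0, 0, 5, 0), c(0, 0, 0, 0))
  f <- normalize_scores(s)
  expect_equal(f[1, ], c(0.5, 0.25, 0.25, 0))
  expect_equal(f[2, 3], 1)
  expect_true(all(is.na(f[3, ])))
})

test_that("split-half validation passes on clean data and reports congruences", {
  tt <- make_tensor(ns = 16, k = 2, noise = 0.01, seed = 9)
  sh <- split_half_validate(tt$tensor, 2, seed = 21, n_starts = 3,
                            max_iter = 300)
  expect_true(sh$pass)
  expect_true(all(sh$congruence >= 0.95))
  expect_length(sh$congruence, 2)
  expect_error(split_half_validate(make_tensor(ns = 6, k = 1)$tensor, 1),
               "at least 8")
})

test_that("core consistency is near 100 for a clean trilinear fit", {
  tt <- make_tensor(ns = 10, k = 2, noise = 0.01, seed = 12)
  fit <- fit_parafac(tt$tensor, 2, tol = 1e-10, max_iter = 300, n_starts = 3, seed = 2)
  expect_gt(core_consistency(fit, tt$tensor), 90)
})

test_that("models serialize to plain text and reconstitute identically", {
  tt <- make_tensor(ns = 8, k = 2, noise = 0.01, seed = 13)
  fit <- fit_parafac(tt$tensor, 2, tol = 1e-9, max_iter = 150, n_starts = 2, seed = 6)
  dir <- tempfile()
  write_parafac_model(fit, dir)
  back <- read_parafac_model(dir)
  expect_equal(back$ex_loadings, fit$ex_loadings)
  expect_equal(back$em_loadings, fit$em_loadings)
  expect_equal(unname(back$scores), unname(fit$scores))
  expect_equal(back$sse_history, fit$sse_history)
  expect_identical(back$converged, fit$converged)
  expect_equal(back$explained_variance, fit$explained_variance)
})
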