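make_screen_inputs <- function(m, optics) {
  rownames(optics) <- colnames(m)
  list(m = m, o = optics)
}

test_that("perfect monotone pairs are flagged significant with rho 1", {
  n <- 10
  x <- 1:10
  m <- matrix(sqrt(x), 1, n, dimnames = list("f1", paste0("S", 1:n)))
  o <- data.frame(v = as.numeric(x), row.names = paste0("S", 1:n))
  res <- spearman_screen(m, o)
  expect_equal(res$rho, 1)
  expect_lt(res$p, 0.01)
  expect_true(res$significant_positive)
  res2 <- spearman_screen(-m, o)
  expect_equal(res2$rho, -1)
  expect_true(res2$significant_negative)
})

test_that("constant rows are reported missing, never significant", {
  n <- 12
  m <- rbind(f1 = rep(0.5, n), f2 = rnorm(n))
  colnames(m) <- paste0("S", 1:n)
  o <- data.frame(v = rnorm(n), row.names = paste0("S", 1:n))
  res <- spearman_screen(m, o)
  expect_true(is.na(res$rho[res$formula == "f1"]))
  expect_false(res$significant_positive[res$formula == "f1"])
  expect_false(res$significant_negative[res$formula == "f1"])
})

test_that("small-n p-values match the exhaustive permutation oracle", {
  set.seed(19)
  for (rep in 1:3) {
    x <- rnorm(8); y <- rnorm(8)
    m <- matrix(y, 1, 8, dimnames = list("f1", paste0("S", 1:8)))
    o <- data.frame(v = x, row.names = paste0("S", 1:8))
    res <- spearman_screen(m, o, min_n = 5)
    expect_lt(abs(res$p - oracle_spearman_exact_p(y, x)), 1e-12)
  }
})

test_that("large-n rho and p agree with the t-approximation reference", {
  set.seed(20)
  n <- 57
  y <- rnorm(n); x <- 0.5 * y + rnorm(n)
  m <- matrix(y, 1, n, dimnames = list("f1", paste0("S", 1:n)))
  o <- data.frame(v = x, row.names = paste0("S", 1:n))
  res <- spearman_screen(m, o)
  ct <- suppressWarnings(stats::cor.test(y, x, method = "spearman", exact = FALSE))
  expect_equal(res$rho, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(res$p, ct$p.value, tolerance = 1e-12)
})

test_that("rho and p are invariant to strictly increasing transforms", {
  set.seed(21)
  n <- 30
  y <- rlnorm(n); x <- rnorm(n)
  base <- spearman_screen(matrix(y, 1, n, dimnames = list("f", paste0("S", 1:n))),
                          data.frame(v = x, row.names = paste0("S", 1:n)))
  tr <- spearman_screen(matrix(log(y) + 3, 1, n,
                               dimnames = list("f", paste0("S", 1:n))),
                        data.frame(v = exp(x), row.names = paste0("S", 1:n)))
  expect_equal(base$rho, tr$rho)
  expect_equal(base$p, tr$p)
})

test_that("q-values are a clearly separate BH extension", {
  set.seed(22)
  n <- 20
  m <- matrix(rnorm(5 * n), 5, n, dimnames = list(paste0("f", 1:5), paste0("S", 1:n)))
  o <- data.frame(a = rnorm(n), b = rnorm(n), row.names = paste0("S", 1:n))
  res <- spearman_screen(m, o)
  expect_true(all(res$q_bh >= res$p, na.rm = TRUE))
  expect_equal(res$q_bh, stats::p.adjust(res$p, "BH"))
})

# A tiny screened dataset with planted structure for the summary products.
planted_results <- function() {
  ann <- annotate_formulae(c("C10H8O5", "C20H14O6", "C15H24O4", "C12H22N2O3",
                             "C6H12O6", "C16H32O2"))
  res <- data.frame(
    formula = rep(ann$formula, 2),
    property = rep(c("c1", "c2"), each = 6),
    rho = c(0.9, 0.8, 0.7, -0.8, 0.1, 0.85,  0.9, 0.1, 0.1, 0.1, 0.1, 0.1),
    p = c(0.001, 0.002, 0.003, 0.004, 0.5, 0.005,
          0.001, 0.5, 0.5, 0.5, 0.5, 0.5),
    q_bh = NA_real_, n_used = 20,
    significant_positive = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE,
                             TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    significant_negative = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE,
                             rep(FALSE, 6))
  )
  list(ann = ann, res = res)
}

test_that("class summaries count planted memberships exactly and reconcile", {
  pr <- planted_results()
  cs <- summarize_classes(pr$res, pr$ann, "positive")
  g <- function(prop, cat, col) cs[cs$property == prop & cs$category == cat, col]
  expect_identical(g("c1", "all", "n_significant"), 4L)
  expect_identical(g("c2", "all", "n_significant"), 1L)
  expect_identical(g("c1", "all", "n_significant"),
                   g("c1", "cho_only", "n_significant") +
                     g("c1", "contains_nsp", "n_significant"))
  neg <- summarize_classes(pr$res, pr$ann, "negative")
  expect_identical(neg[neg$property == "c1" & neg$category == "all",
                       "n_significant"], 1L)
  expect_identical(neg[neg$property == "c2" & neg$category == "all",
                       "n_significant"], 0L)
  # mean m/z of the significant set is the mean of its ion masses
  sig <- pr$ann[pr$ann$formula %in%
                  pr$res$formula[pr$res$property == "c1" &
                                   pr$res$significant_positive], ]
  expect_equal(g("c1", "all", "mean_mz"), mean(sig$ion_mz))
})

test_that("intensity-weighted percents respond to the weight vector", {
  pr <- planted_results()
  w <- stats::setNames(c(10, 1, 1, 1, 1, 1), pr$ann$formula)
  cs <- summarize_classes(pr$res, pr$ann, "positive", weights = w)
  all_row <- cs[cs$property == "c1" & cs$category == "all", ]
  expect_equal(all_row$intensity_pct, 100 * (10 + 1 + 1 + 1) / 15)
  expect_equal(all_row$count_pct, 100 * 4 / 6)
})

test_that("shared-formula matrices count set intersections", {
  pr <- planted_results()
  sm <- shared_formula_matrix(pr$res, "positive")
  expect_identical(sm["c1", "c1"], 4L)
  expect_identical(sm["c2", "c2"], 1L)
  expect_identical(sm["c1", "c2"], 1L)      # C10H8O5 shared
  expect_true(isSymmetric(sm))
  # disjoint sets give zero off-diagonals
  res2 <- pr$res
  res2$significant_positive[res2$property == "c2"] <- FALSE
  res2$significant_positive[res2$property == "c2" & res2$formula == "C6H12O6"] <- TRUE
  expect_identical(shared_formula_matrix(res2)["c1", "c2"], 0L)
})

test_that("distribution profiles integrate to the significant counts", {
  pr <- planted_results()
  prof <- distribution_profiles(pr$res, pr$ann, "positive")
  mass_c1 <- prof[prof$property == "c1" & prof$variable == "mass", ]
  expect_identical(sum(mass_c1$count), 4L)
  expect_false(any(mass_c1$empty_set))
  # a property with an empty set is flagged, zero counts
  res0 <- pr$res
  res0$significant_positive <- FALSE
  prof0 <- distribution_profiles(res0, pr$ann, "positive")
  expect_true(all(prof0$empty_set))
  expect_identical(sum(prof0$count), 0L)
  # weights equal to 1 reproduce counts
  expect_equal(mass_c1$weight, as.numeric(mass_c1$count))
})

test_that("van Krevelen exports carry coordinates, class and stats", {
  pr <- planted_results()
  vk <- van_krevelen_export(pr$res, pr$ann, "c1", "positive")
  expect_identical(nrow(vk), 4L)
  expect_true(all(c("oc_ratio", "hc_ratio", "compound_class", "rho", "p")
                  %in% names(vk)))
  idx <- match(vk$formula, pr$ann$formula)
  expect_equal(vk$oc_ratio, pr$ann$oc_ratio[idx])
  empty <- van_krevelen_export(pr$res, pr$ann, "c2", "negative")
  expect_identical(nrow(empty), 0L)
  expect_identical(names(empty), names(vk))
})
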