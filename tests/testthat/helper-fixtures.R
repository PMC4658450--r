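# Shared fixtures, built in code and cached for the test run.

small_generator_config <- function(...) {
  defaults <- list(
    n_samples = 20, n_formulae = 300, n_noise_peaks = 50,
    plant_drivers = c("c1", "suva254"),
    plant_rhos = rep(c(0.9, 0.8, -0.8), times = 4),
    n_overlap = 6
  )
  do.call(generator_config, utils::modifyList(defaults, list(...)))
}

.fixture_cache <- new.env()

get_small_cohort <- function() {
  if (is.null(.fixture_cache$coh)) {
    .fixture_cache$coh <- generate_cohort(small_generator_config(), seed = 11)
  }
  .fixture_cache$coh
}

process_eems <- function(coh) {
  ids <- coh$samples$sample_id
  out <- lapply(seq_along(ids), function(i) {
    x <- blank_subtract(coh$eems[[i]], coh$blanks[[i]])
    x <- inner_filter_correct(x, coh$absorbance[[i]])
    excise_scatter(x)
  })
  names(out) <- ids
  out
}

# EEM from an intensity function of (ex, em)
toy_eem <- function(ex, em, f, ...) {
  eem(ex, em, outer(ex, em, f), ...)
}

# Independent oracle: all permutations of 1..n by recursive insertion
# (different algorithm from the package's iterative builder).
oracle_perms <- function(n) {
  rec <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in rec(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  rec(seq_len(n))
}

# Independent oracle for the exact two-sided Spearman permutation p-value.
oracle_spearman_exact_p <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  obs <- stats::cor(rx, ry)
  vals <- vapply(oracle_perms(length(x)),
                 function(p) stats::cor(rx, ry[p]), numeric(1))
  mean(abs(vals) >= abs(obs) - 1e-12)
}

# Random CHNOSP formula counts within assignment bounds
random_formula_counts <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(
    c = sample(1:60, n, replace = TRUE),
    h = sample(1:120, n, replace = TRUE),
    n = sample(0:4, n, replace = TRUE),
    o = sample(0:40, n, replace = TRUE),
    s = sample(0:2, n, replace = TRUE),
    p = sample(0:1, n, replace = TRUE)
  )
}
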