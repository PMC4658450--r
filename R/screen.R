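# Spearman rank screening of every formula's normalized intensity against
# every optical property, plus the derived summary products: class summaries,
# shared-formula matrices, van Krevelen sets, and distribution profiles.

.perm_cache <- new.env(parent = emptyenv())

# All n! permutations of 1..n as an (n! x n) matrix, built incrementally.
.permutations <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  P <- matrix(1L, 1, 1)
  if (n > 1) {
    for (m in 2:n) {
      old <- P
      P <- matrix(0L, nrow(old) * m, m)
      row <- 1
      for (pos in seq_len(m)) {
        # insert value m at column position pos
        left <- if (pos > 1) old[, seq_len(pos - 1), drop = FALSE] else NULL
        right <- if (pos <= m - 1) old[, pos:(m - 1), drop = FALSE] else NULL
        P[row:(row + nrow(old) - 1), ] <- cbind(left, m, right)
        row <- row + nrow(old)
      }
    }
  }
  .perm_cache[[key]] <- P
  P
}

# Exact two-sided permutation p-value for Spearman's rho at small n:
# enumerates all n! orderings of one variable's ranks.
.spearman_exact_p <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  rxc <- rx - mean(rx); ryc <- ry - mean(ry)
  den <- sqrt(sum(rxc^2) * sum(ryc^2))
  if (den == 0) return(NA_real_)
  obs <- sum(rxc * ryc) / den
  P <- .permutations(n)
  num <- matrix(ryc[P], nrow(P), n) %*% rxc
  rho_perm <- as.numeric(num) / den
  mean(abs(rho_perm) >= abs(obs) - 1e-12)
}

#' Spearman rank screen of formula intensities against optical properties
#'
#' Computes, for every (formula, property) pair, Spearman's rho with
#' average-rank tie handling and a two-sided p-value: exact permutation over
#' all n! orderings for n <= 9, the t-distribution approximation
#' \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}} otherwise. Pairs with a constant
#' vector (for instance formula rows consisting entirely of the SDL fill) are
#' reported with missing rho/p and never flagged significant. Significance
#' flags are set at raw two-sided \code{p < alpha} with the matching sign —
#' the screen applies no multiple-testing correction by design; a
#' Benjamini-Hochberg q-value column (\code{q_bh}) is additionally reported as
#' a clearly separate extension and is not used by any summary.
#'
#' @param normalized Numeric matrix (formula x sample), typically
#'   \code{peak_matrix$normalized}; rownames are formula strings.
#' @param optics Data frame of optical properties, one row per sample (rownames
#'   or a \code{sample_id} column matching the matrix columns); numeric
#'   columns are screened.
#' @param alpha Significance level (default 0.01, the 99 percent confidence screen).
#' @param min_n Minimum overlapping samples per pair (default 5); properties
#'   with fewer complete samples are skipped with a message.
#' @return Long data frame: \code{formula, property, rho, p, q_bh, n_used,
#'   significant_positive, significant_negative}.
#' @export
spearman_screen <- function(normalized, optics, alpha = 0.01, min_n = 5) {
  if (!is.null(optics$sample_id)) {
    rownames(optics) <- optics$sample_id
    optics$sample_id <- NULL
  }
  optics <- optics[, vapply(optics, is.numeric, logical(1)), drop = FALSE]
  common <- intersect(colnames(normalized), rownames(optics))
  if (length(common) < min_n) stop("fewer than min_n overlapping samples")
  m <- normalized[, common, drop = FALSE]
  optics <- optics[common, , drop = FALSE]
  eps <- 1e-12
  row_const <- apply(m, 1, function(v) max(v) - min(v) <= eps * max(abs(v), 1))
  res <- list()
  for (prop in colnames(optics)) {
    y <- optics[[prop]]
    use <- !is.na(y)
    n <- sum(use)
    if (n < min_n) {
      message("skipping property ", prop, ": fewer than ", min_n, " samples")
      next
    }
    yv <- y[use]
    prop_const <- max(yv) - min(yv) <= eps * max(abs(yv), 1)
    mm <- m[, use, drop = FALSE]
    fr <- t(apply(mm, 1, rank))
    pr <- rank(yv)
    rho <- suppressWarnings(as.numeric(stats::cor(t(fr), pr)))
    rho[row_const | prop_const] <- NA_real_
    if (n <= 9) {
      p <- vapply(seq_len(nrow(mm)), function(i) {
        if (is.na(rho[i])) NA_real_ else .spearman_exact_p(mm[i, ], yv)
      }, numeric(1))
    } else {
      r2 <- pmin(rho^2, 1)
      tt <- abs(rho) * sqrt((n - 2) / pmax(1 - r2, .Machine$double.eps))
      tt[r2 >= 1] <- Inf
      p <- 2 * stats::pt(-tt, n - 2)
      p <- pmin(p, 1)
    }
    res[[prop]] <- data.frame(
      formula = rownames(m), property = prop, rho = rho, p = p,
      n_used = n,
      significant_positive = !is.na(p) & p < alpha & rho > 0,
      significant_negative = !is.na(p) & p < alpha & rho < 0,
      row.names = NULL
    )
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$q_bh <- stats::p.adjust(out$p, method = "BH")
  out[c("formula", "property", "rho", "p", "q_bh", "n_used",
        "significant_positive", "significant_negative")]
}

.sig_flag <- function(results, direction) {
  direction <- match.arg(direction, c("positive", "negative"))
  if (direction == "positive") results$significant_positive else
    results$significant_negative
}

.category_table <- function(ann) {
  cats <- list(
    all = rep(TRUE, nrow(ann)),
    cho_only = ann$cho_only,
    chon = ann$has_n,
    chos = ann$has_s,
    chop = ann$has_p,
    contains_nsp = ann$has_n | ann$has_s | ann$has_p
  )
  for (cl in COMPOUND_CLASSES) cats[[cl]] <- ann$compound_class == cl
  cats
}

#' Summarize significant formulae by elemental group and compound class
#'
#' Reproduces the class-summary table shape: for each property and each
#' category (CHO-only, CHON, CHOS, CHOP, contains N/S/P, and the compound
#' classes), the count of significant formulae in the chosen direction, the
#' count as a percent of the category's cohort total, the intensity-weighted
#' percent of the category, and the mean ion mass of the significant set.
#' Heteroatom groups are membership-based (CHON means "contains N", whatever
#' the S/P content), so CHO-only + contains-N/S/P reconciles to the total.
#'
#' @param results Output of [spearman_screen()].
#' @param annotations Formula annotations ([annotate_formulae()] layout) for
#'   every formula in the cohort.
#' @param direction \code{"positive"} (r > 0) or \code{"negative"}.
#' @param weights Optional named numeric vector of per-formula intensity
#'   weights (e.g. summed normalized intensity); defaults to equal weights.
#' @return Long data frame: \code{property, category, n_category,
#'   n_significant, count_pct, intensity_pct, mean_mz}.
#' @export
summarize_classes <- function(results, annotations, direction = "positive",
                              weights = NULL) {
  sig <- .sig_flag(results, direction)
  ann <- annotations[match(unique(results$formula), annotations$formula), ]
  if (is.null(weights)) {
    weights <- stats::setNames(rep(1, nrow(ann)), ann$formula)
  }
  w <- weights[ann$formula]
  cats <- .category_table(ann)
  props <- unique(results$property)
  rows <- list()
  for (prop in props) {
    sel <- results$property == prop & sig
    in_sig <- ann$formula %in% results$formula[sel]
    for (cat in names(cats)) {
      inc <- cats[[cat]]
      n_cat <- sum(inc)
      n_sig <- sum(inc & in_sig)
      rows[[length(rows) + 1]] <- data.frame(
        property = prop, category = cat,
        n_category = n_cat, n_significant = n_sig,
        count_pct = if (n_cat > 0) 100 * n_sig / n_cat else 0,
        intensity_pct = if (n_cat > 0 && sum(w[inc]) > 0)
          100 * sum(w[inc & in_sig]) / sum(w[inc]) else 0,
        mean_mz = if (n_sig > 0) mean(ann$ion_mz[inc & in_sig]) else NA_real_
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Shared-formula count matrix across properties
#'
#' Entry (i, j) is the number of formulae significantly associated (in the
#' chosen direction) with both property i and property j; the diagonal is the
#' size of each property's significant set.
#'
#' @inheritParams summarize_classes
#' @return Symmetric integer matrix (property x property).
#' @export
shared_formula_matrix <- function(results, direction = "positive") {
  sig <- .sig_flag(results, direction)
  props <- unique(results$property)
  sets <- lapply(props, function(p) results$formula[results$property == p & sig])
  names(sets) <- props
  k <- length(props)
  m <- matrix(0L, k, k, dimnames = list(props, props))
  for (i in seq_len(k)) for (j in i:k) {
    m[i, j] <- m[j, i] <- length(intersect(sets[[i]], sets[[j]]))
  }
  m
}

#' Mass / H:C / AI-mod distribution profiles of significant sets
#'
#' Binned counts and intensity-weighted totals of ion mass, H/C ratio, and
#' AI-mod over each property's significant set, emitted tidy for any plotting
#' layer. Properties whose significant set is empty yield zero-count rows
#' flagged \code{empty_set}.
#'
#' @inheritParams summarize_classes
#' @param mass_width,hc_width,ai_width Bin widths for the three variables.
#' @return Tidy data frame: \code{property, variable, bin_lo, bin_mid, count,
#'   weight, empty_set}.
#' @export
distribution_profiles <- function(results, annotations, direction = "positive",
                                  weights = NULL, mass_width = 50,
                                  hc_width = 0.1, ai_width = 0.05) {
  sig <- .sig_flag(results, direction)
  ann <- annotations
  if (is.null(weights)) {
    weights <- stats::setNames(rep(1, nrow(ann)), ann$formula)
  }
  vars <- list(
    mass = list(v = ann$ion_mz, w = mass_width),
    hc_ratio = list(v = ann$hc_ratio, w = hc_width),
    ai_mod = list(v = ann$ai_mod, w = ai_width)
  )
  props <- unique(results$property)
  rows <- list()
  for (prop in props) {
    set <- results$formula[results$property == prop & sig]
    idx <- match(set, ann$formula)
    for (vn in names(vars)) {
      v <- vars[[vn]]$v; wd <- vars[[vn]]$w
      lo0 <- floor(min(v) / wd) * wd
      breaks <- seq(lo0, max(v) + wd, by = wd)
      if (length(idx)) {
        bin <- findInterval(v[idx], breaks, rightmost.closed = TRUE)
        cnt <- tabulate(bin, nbins = length(breaks) - 1)
        wt <- vapply(seq_len(length(breaks) - 1), function(b) {
          sum(weights[set[bin == b]])
        }, numeric(1))
      } else {
        cnt <- integer(length(breaks) - 1)
        wt <- numeric(length(breaks) - 1)
      }
      rows[[length(rows) + 1]] <- data.frame(
        property = prop, variable = vn,
        bin_lo = breaks[-length(breaks)],
        bin_mid = breaks[-length(breaks)] + wd / 2,
        count = cnt, weight = wt, empty_set = length(idx) == 0
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export a van Krevelen point set for one property
#'
#' The significant set of a property, in the chosen direction, as a tidy
#' table of (O/C, H/C) coordinates with compound class, AI-mod, ion mass,
#' intensity weight, and the screening statistics — suitable for any plotting
#' layer. An empty set yields an empty table with the full header.
#'
#' @inheritParams summarize_classes
#' @param property Property name as it appears in \code{results$property}.
#' @export
van_krevelen_export <- function(results, annotations, property,
                                direction = "positive", weights = NULL) {
  sig <- .sig_flag(results, direction)
  sel <- results$property == property & sig
  set <- results[sel, c("formula", "rho", "p")]
  idx <- match(set$formula, annotations$formula)
  if (is.null(weights)) {
    weights <- stats::setNames(rep(1, nrow(annotations)), annotations$formula)
  }
  data.frame(
    formula = set$formula,
    oc_ratio = annotations$oc_ratio[idx],
    hc_ratio = annotations$hc_ratio[idx],
    ai_mod = annotations$ai_mod[idx],
    ion_mz = annotations$ion_mz[idx],
    compound_class = annotations$compound_class[idx],
    weight = as.numeric(weights[set$formula]),
    rho = set$rho, p = set$p,
    row.names = NULL
  )
}
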