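# Nonnegative trilinear PARAFAC of the sample x excitation x emission tensor.
# Missing cells (scatter excision, unscanned ragged range) carry zero weight
# in the least-squares residual; the compiled weighted-HALS kernel in
# src/parafac_wals.cpp does the per-sweep work.

#' Stack EEMs into a sample x excitation x emission tensor
#'
#' All EEMs must share grids. The emission axis is trimmed to \code{em_range}
#' (default 300-600 nm): the acquisition scheme scans emission only from
#' ex+10 to ex+250 nm, so on the full union grid more than half of each
#' sample's cells are unscanned; fitting on a validated subrange keeps the
#' per-sample missing fraction below 50%.
#'
#' @param eems List of [eem] objects on identical grids.
#' @param sample_ids Character vector of sample identifiers.
#' @param em_range Length-2 numeric; emission window (nm) retained for fitting.
#' @param ex_range Optional excitation window (nm).
#' @param em_step Keep every \code{em_step}-th emission point (default 2,
#'   i.e. a 4 nm fitting grid for a 2 nm acquisition grid — the customary
#'   thinning for EEM PARAFAC, which conditions the fit and costs nothing at
#'   the 40-60 nm widths of fluorophore emission bands).
#' @return An object of class \code{eem_tensor}: list with \code{values}
#'   (3-way array), \code{mask} (TRUE = missing), grids and ids.
#' @export
eem_tensor <- function(eems, sample_ids = names(eems),
                       em_range = c(300, 600), ex_range = NULL, em_step = 2) {
  if (length(eems) < 2) stop("need at least 2 samples")
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_along(eems))
  ref <- eems[[1]]
  for (e in eems[-1]) .check_same_grids(ref, e)
  keep_em <- ref$emission >= em_range[1] & ref$emission <= em_range[2]
  keep_em <- keep_em & (cumsum(keep_em) - 1) %% em_step == 0
  keep_ex <- if (is.null(ex_range)) rep(TRUE, length(ref$excitation)) else {
    ref$excitation >= ex_range[1] & ref$excitation <= ex_range[2]
  }
  ex <- ref$excitation[keep_ex]
  em <- ref$emission[keep_em]
  ns <- length(eems)
  values <- array(0, c(ns, length(ex), length(em)))
  mask <- array(TRUE, c(ns, length(ex), length(em)))
  for (i in seq_len(ns)) {
    values[i, , ] <- eems[[i]]$intensity[keep_ex, keep_em]
    mask[i, , ] <- eems[[i]]$mask[keep_ex, keep_em]
  }
  values[mask] <- 0
  frac <- apply(mask, 1, mean)
  if (any(frac >= 0.5)) {
    warning("missing fraction >= 50% for sample(s): ",
            paste(sample_ids[frac >= 0.5], collapse = ", "))
  }
  structure(list(values = values, mask = mask, sample_ids = sample_ids,
                 excitation = ex, emission = em),
            class = "eem_tensor")
}

#' @export
print.eem_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("EEM tensor: %d samples x %d ex x %d em, %.1f%% missing\n",
              d[1], d[2], d[3], 100 * mean(x$mask)))
  invisible(x)
}

#' Normalize each sample slab to unit maximum
#'
#' Divides every sample's observed intensities by their maximum so each sample
#' contributes comparably to the fit; the factors are returned so scores can
#' be mapped back to original intensities. Samples with a non-positive
#' maximum are excluded (with a message).
#'
#' @param t An [eem_tensor].
#' @return List with the normalized \code{tensor}, \code{scale_factors}
#'   (named by sample), and \code{excluded} sample ids.
#' @export
normalize_for_fit <- function(t) {
  ns <- dim(t$values)[1]
  mx <- vapply(seq_len(ns), function(i) {
    v <- t$values[i, , ][!t$mask[i, , ]]
    if (length(v) == 0) -Inf else max(v)
  }, numeric(1))
  bad <- !(mx > 0)
  if (any(bad)) {
    message("excluding sample(s) with non-positive maximum: ",
            paste(t$sample_ids[bad], collapse = ", "))
  }
  keep <- which(!bad)
  out <- t
  out$values <- t$values[keep, , , drop = FALSE]
  out$mask <- t$mask[keep, , , drop = FALSE]
  out$sample_ids <- t$sample_ids[keep]
  for (j in seq_along(keep)) out$values[j, , ] <- out$values[j, , ] / mx[keep[j]]
  out$values[out$mask] <- 0
  list(tensor = out,
       scale_factors = stats::setNames(mx[keep], t$sample_ids[keep]),
       excluded = t$sample_ids[bad])
}

# Khatri-Rao product with row index i + nrow(B)*(j-1) -> B[i,]*C[j,]
.khatri_rao <- function(C, B) {
  B[rep(seq_len(nrow(B)), nrow(C)), , drop = FALSE] *
    C[rep(seq_len(nrow(C)), each = nrow(B)), , drop = FALSE]
}

# One fit from one start, via the compiled weighted-HALS kernel. unf carries
# the three mode unfoldings of the data and observation weights. monotone
# selects the projected-ridge update whose SSE trajectory is non-increasing
# by construction (used for the recorded fit); plain ridge updates are used
# for exploration.
.parafac_single <- function(unf, dims, k, tol, max_iter, ridge_rel,
                            monotone = FALSE, init = NULL) {
  ns <- dims[1]; nex <- dims[2]; nem <- dims[3]
  if (is.null(init)) {
    init <- list(A = matrix(stats::runif(ns * k), ns, k),
                 B = matrix(stats::runif(nex * k), nex, k),
                 C = matrix(stats::runif(nem * k), nem, k))
  }
  fit <- .parafac_wals_cpp(unf$XA, unf$OA, unf$XB, unf$OB, unf$XC, unf$OC,
                           init$A, init$B, init$C, tol, max_iter,
                           ridge_rel, monotone)
  sse <- fit$sse_history[length(fit$sse_history)]
  list(A = fit$A, B = fit$B, C = fit$C, sse = sse,
       sse_history = fit$sse_history, iterations = fit$iterations,
       converged = fit$converged,
       explained_variance = 1 - sse / unf$ss_tot)
}

# Precompute the three mode unfoldings (values and 0/1 observation weights).
.parafac_unfoldings <- function(t) {
  dims <- dim(t$values)
  arr <- t$values
  obs <- array(as.numeric(!t$mask), dims)
  arr[t$mask] <- 0
  list(
    XA = matrix(arr, dims[1]), OA = matrix(obs, dims[1]),
    XB = matrix(aperm(arr, c(2, 1, 3)), dims[2]),
    OB = matrix(aperm(obs, c(2, 1, 3)), dims[2]),
    XC = matrix(aperm(arr, c(3, 1, 2)), dims[3]),
    OC = matrix(aperm(obs, c(3, 1, 2)), dims[3]),
    ss_tot = sum(arr[!t$mask]^2)
  )
}

#' Fit a nonnegative PARAFAC model to an EEM tensor
#'
#' Trilinear alternating-least-squares fit with nonnegativity in all three
#' modes; missing cells carry zero weight in the residual. The fit proceeds
#' in two stages: an exploratory stage (multi-start burn-in, then ridge-damped
#' refinement of the best start, with SSE-guarded line-search acceleration)
#' and a recorded stage of projected-ridge sweeps starting from the
#' exploratory optimum, whose observed-cell SSE trajectory is non-increasing
#' by construction and is the one reported. Components are ordered by
#' decreasing total score (their proportional contribution to total
#' fluorescence); excitation and emission loadings are scaled to unit maximum
#' per component with the scale absorbed into the scores. A numerical
#' monotonicity violation beyond 1e-8 relative would trigger a warning and be
#' flagged on the model.
#'
#' @param t An [eem_tensor], normally normalized via [normalize_for_fit()].
#' @param k Number of components (>= 1 and at most the smallest mode).
#' @param tol Relative SSE-change convergence tolerance.
#' @param max_iter Maximum outer iterations for the refined fit.
#' @param n_starts Number of random initializations.
#' @param burnin Each start is first run for this many sweeps and only the
#'   best (lowest SSE) is refined to convergence — the usual multi-start
#'   economy for ALS fits.
#' @param polish Iteration cap for the final recorded (projected-ridge)
#'   phase, which starts at the exploratory optimum and therefore needs only
#'   a short run; its SSE trajectory is the one reported and asserted.
#' @param seed RNG seed; the fit is bit-for-bit reproducible given
#'   \code{(seed, n_starts, tol)}.
#' @param ridge_rel Identifiability ridge, as a fraction of each component's
#'   maximum observed design energy within a mode. Loading cells observed
#'   only where the component carries almost no signal (a consequence of the
#'   ragged emission scan plus scatter excision) are nearly unidentifiable —
#'   any value fits the observed cells equally well — and would otherwise
#'   carry arbitrary noise-driven mass; the ridge damps them toward zero
#'   while leaving well-observed cells essentially untouched. The recorded
#'   fit uses projected ridge updates (damping applied only where it does not
#'   increase the observed SSE), so the reported SSE trajectory is
#'   non-increasing by construction. Set to 0 to disable.
#' @return An object of class \code{parafac_model}: scores (sample x
#'   component), ex/em loadings, explained variance, iteration/convergence
#'   info, and the SSE history of the winning start.
#' @export
fit_parafac <- function(t, k, tol = 1e-8, max_iter = 2500, n_starts = 10,
                        seed = 1, ridge_rel = 1e-4, burnin = 50,
                        polish = 150) {
  dims <- dim(t$values)
  if (k < 1) stop("k must be >= 1")
  if (k > min(dims)) stop("k exceeds the smallest tensor mode")
  unf <- .parafac_unfoldings(t)
  set.seed(seed)
  # Initialization: multi-start burn-in, then ridge-damped refinement of the
  # best start. This exploratory solution only seeds the recorded fit below.
  best <- NULL
  for (s in seq_len(n_starts)) {
    fit <- .parafac_single(unf, dims, k, tol, min(burnin, max_iter), ridge_rel)
    if (is.null(best) || fit$sse < best$sse) best <- fit
  }
  explore_iter <- best$iterations
  if (max_iter > burnin) {
    best <- .parafac_single(unf, dims, k, tol, max_iter - burnin, ridge_rel,
                            init = best)
    explore_iter <- explore_iter + best$iterations
  }
  # Recorded fit: projected-ridge updates from the exploratory solution;
  # every sweep is non-increasing in observed SSE by construction.
  best <- .parafac_single(unf, dims, k, tol, polish, ridge_rel,
                          monotone = TRUE, init = best)
  ord <- order(colSums(best$A), decreasing = TRUE)
  dimnames(best$A) <- list(t$sample_ids, NULL)
  hist <- best$sse_history
  # relative tolerance with an absolute floor tied to the data scale, so a
  # numerically-zero residual (noiseless data) is not held to 1e-8 of itself
  mono_ok <- all(diff(hist) <=
                   1e-8 * pmax(hist[-length(hist)], 1e-12 * unf$ss_tot))
  if (!mono_ok) warning("residual SSE increased during ALS iterations")
  structure(list(
    n_components = k,
    scores = best$A[, ord, drop = FALSE],
    ex_loadings = best$B[, ord, drop = FALSE],
    em_loadings = best$C[, ord, drop = FALSE],
    explained_variance = best$explained_variance,
    iterations = best$iterations,
    exploratory_iterations = explore_iter,
    converged = best$converged,
    sse = best$sse,
    sse_history = hist,
    sse_monotone = mono_ok,
    seed = seed, tol = tol, n_starts = n_starts, ridge_rel = ridge_rel,
    burnin = burnin,
    excitation = t$excitation, emission = t$emission,
    sample_ids = t$sample_ids
  ), class = "parafac_model")
}

#' @export
print.parafac_model <- function(x, ...) {
  cat(sprintf(
    "PARAFAC model: %d components, %d samples, EV %.4f, %d iterations (%s)\n",
    x$n_components, nrow(x$scores), x$explained_variance, x$iterations,
    if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Tucker congruence between loading vectors
#'
#' Cosine similarity; for matrices, congruence is computed column-pairwise.
#'
#' @param a,b Numeric vectors or matrices (columns = components).
#' @return Scalar or matrix of congruence coefficients.
#' @export
tucker_congruence <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  na <- sqrt(colSums(a^2)); nb <- sqrt(colSums(b^2))
  out <- crossprod(a, b) / outer(na, nb)
  if (all(dim(out) == 1)) out[1, 1] else out
}

# Greedy matching of components across two fits by the smaller of the ex- and
# em-mode congruences. Returns data frame (comp_a, comp_b, congruence).
.match_components <- function(ex_a, em_a, ex_b, em_b) {
  cc <- pmin(tucker_congruence(ex_a, ex_b), tucker_congruence(em_a, em_b))
  cc <- matrix(cc, ncol(ex_a), ncol(ex_b))
  k <- min(dim(cc))
  pairs <- data.frame(comp_a = integer(k), comp_b = integer(k),
                      congruence = numeric(k))
  for (i in seq_len(k)) {
    ij <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    pairs[i, ] <- c(ij[1], ij[2], cc[ij[1], ij[2]])
    cc[ij[1], ] <- -Inf
    cc[, ij[2]] <- -Inf
  }
  pairs[order(pairs$comp_a), ]
}

#' Split-half validation of a PARAFAC model
#'
#' Samples are randomly partitioned into two halves; independent models are
#' fitted to each; components are greedily matched across halves by spectral
#' congruence. The report carries, per component, the smaller of the
#' excitation- and emission-mode Tucker congruences; the model passes when
#' all are at or above \code{threshold}.
#'
#' @param t An [eem_tensor] with at least 8 samples.
#' @param k Number of components.
#' @param seed RNG seed controlling the partition and the half-fits.
#' @param threshold Congruence pass threshold (default 0.95).
#' @param n_starts,tol,max_iter,ridge_rel,burnin Fit parameters for the
#'   half-models.
#' @return List with \code{congruence} (per matched component), \code{pass},
#'   and the two half assignments.
#' @export
split_half_validate <- function(t, k, seed = 1, threshold = 0.95,
                                n_starts = 4, tol = 1e-7, max_iter = 600,
                                ridge_rel = 1e-4, burnin = 50) {
  ns <- dim(t$values)[1]
  if (ns < 8) stop("split-half validation needs at least 8 samples")
  set.seed(seed)
  perm <- sample.int(ns)
  half1 <- sort(perm[seq_len(floor(ns / 2))])
  half2 <- sort(perm[(floor(ns / 2) + 1):ns])
  sub <- function(idx) {
    out <- t
    out$values <- t$values[idx, , , drop = FALSE]
    out$mask <- t$mask[idx, , , drop = FALSE]
    out$sample_ids <- t$sample_ids[idx]
    out
  }
  f1 <- fit_parafac(sub(half1), k, tol = tol, max_iter = max_iter,
                    n_starts = n_starts, seed = seed + 1,
                    ridge_rel = ridge_rel, burnin = burnin)
  f2 <- fit_parafac(sub(half2), k, tol = tol, max_iter = max_iter,
                    n_starts = n_starts, seed = seed + 2,
                    ridge_rel = ridge_rel, burnin = burnin)
  m <- .match_components(f1$ex_loadings, f1$em_loadings,
                         f2$ex_loadings, f2$em_loadings)
  list(congruence = m$congruence, matches = m,
       pass = all(m$congruence >= threshold),
       half1 = t$sample_ids[half1], half2 = t$sample_ids[half2])
}

# Lawson-Hanson active-set NNLS on the normal equations:
# minimize ||Z x - y||^2 s.t. x >= 0, given G = Z'Z and b = Z'y.
.nnls_gram <- function(G, b, tol = NULL) {
  k <- length(b)
  if (is.null(tol)) tol <- 1e-12 * max(diag(G), 1e-300)
  x <- numeric(k)
  P <- rep(FALSE, k)
  for (outer_it in seq_len(30 * k)) {
    w <- b - G %*% x
    cand <- which(!P & w > tol)
    if (length(cand) == 0) break
    P[cand[which.max(w[cand])]] <- TRUE
    repeat {
      s <- numeric(k)
      s[P] <- solve(G[P, P, drop = FALSE], b[P])
      if (all(s[P] > 0)) { x <- s; break }
      drop_set <- P & s <= 0
      alpha <- min(x[drop_set] / (x[drop_set] - s[drop_set]))
      x <- x + alpha * (s - x)
      P[P & x <= tol] <- FALSE
      x[!P] <- 0
    }
  }
  as.numeric(x)
}

#' Project fixed spectral loadings onto EEMs to obtain scores
#'
#' With the model's excitation and emission loadings held fixed, solves a
#' nonnegative least-squares problem per sample for the component scores on
#' the (typically non-normalized) intensities, so scores represent original
#' EEM intensity units. Missing cells are excluded per sample.
#'
#' @param model A [fit_parafac()] model.
#' @param t An [eem_tensor] on the model's grids.
#' @return Matrix (sample x component) of nonnegative scores.
#' @export
project_scores <- function(model, t) {
  if (!isTRUE(all.equal(model$excitation, t$excitation)) ||
      !isTRUE(all.equal(model$emission, t$emission))) {
    stop("tensor grids do not match model loadings")
  }
  Z <- .khatri_rao(model$em_loadings, model$ex_loadings)
  ns <- dim(t$values)[1]
  X1 <- matrix(t$values, ns)
  obs1 <- matrix(!t$mask, ns)
  k <- model$n_components
  out <- matrix(0, ns, k, dimnames = list(t$sample_ids, paste0("C", seq_len(k))))
  for (i in seq_len(ns)) {
    o <- obs1[i, ]
    Zo <- Z[o, , drop = FALSE]
    out[i, ] <- .nnls_gram(crossprod(Zo), crossprod(Zo, X1[i, o]))
  }
  out
}

#' Per-sample component fractions
#'
#' Divides each sample's component scores by their sum, so fractions sum to 1
#' within a sample. Samples with zero total get a missing row.
#'
#' @param scores Matrix (sample x component) of nonnegative scores.
#' @return Matrix of fractions.
#' @export
normalize_scores <- function(scores) {
  tot <- rowSums(scores)
  out <- scores / tot
  out[tot <= 0, ] <- NA_real_
  out
}

#' Core-consistency diagnostic (CORCONDIA)
#'
#' Regresses the (imputed) data tensor onto the Tucker core implied by the
#' fitted loadings and measures how close that core is to superdiagonal.
#' Reported for information only; validation is by split-half.
#'
#' @param model A [parafac_model].
#' @param t The fitted [eem_tensor].
#' @return Core consistency in percent (100 = perfectly trilinear).
#' @export
core_consistency <- function(model, t) {
  k <- model$n_components
  dims <- dim(t$values)
  X1 <- matrix(t$values, dims[1])
  M1 <- model$scores %*% t(.khatri_rao(model$em_loadings, model$ex_loadings))
  X1[!matrix(!t$mask, dims[1])] <- M1[!matrix(!t$mask, dims[1])]
  Ai <- pracma::pinv(model$scores)
  Bi <- pracma::pinv(model$ex_loadings)
  Ci <- pracma::pinv(model$em_loadings)
  Y <- Ai %*% X1                                   # k x (nex*nem)
  Yarr <- array(Y, c(k, dims[2], dims[3]))
  Y2 <- Bi %*% matrix(aperm(Yarr, c(2, 1, 3)), dims[2])   # k x (k*nem)
  Yarr2 <- aperm(array(Y2, c(k, k, dims[3])), c(2, 1, 3)) # k x k x nem
  Y3 <- Ci %*% matrix(aperm(Yarr2, c(3, 1, 2)), dims[3])  # k x (k*k)
  core <- aperm(array(Y3, c(k, k, k)), c(2, 3, 1))
  ideal <- array(0, c(k, k, k))
  for (r in seq_len(k)) ideal[r, r, r] <- 1
  100 * (1 - sum((core - ideal)^2) / k)
}

#' Serialize / load a PARAFAC model as a plain-text bundle
#'
#' Writes one CSV per mode (scores, excitation loadings, emission loadings)
#' plus a JSON metadata file, so loadings are diffable; [read_parafac_model()]
#' reconstitutes an identical model.
#'
#' @param model A [parafac_model].
#' @param dir Directory to write into (created if needed).
#' @export
write_parafac_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  comp <- paste0("C", seq_len(model$n_components))
  w <- function(m, id_col, ids, file) {
    d <- data.frame(ids, m)
    names(d) <- c(id_col, comp)
    utils::write.csv(d, file.path(dir, file), row.names = FALSE)
  }
  w(model$scores, "sample_id", model$sample_ids, "scores.csv")
  w(model$ex_loadings, "excitation_nm", model$excitation, "ex_loadings.csv")
  w(model$em_loadings, "emission_nm", model$emission, "em_loadings.csv")
  meta <- model[c("n_components", "explained_variance", "iterations",
                  "converged", "sse", "sse_monotone", "seed", "tol",
                  "n_starts", "ridge_rel", "burnin")]
  meta$sse_history <- model$sse_history
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_parafac_model
#' @export
read_parafac_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  sc <- utils::read.csv(file.path(dir, "scores.csv"), check.names = FALSE)
  exl <- utils::read.csv(file.path(dir, "ex_loadings.csv"), check.names = FALSE)
  eml <- utils::read.csv(file.path(dir, "em_loadings.csv"), check.names = FALSE)
  model <- list(
    n_components = meta$n_components,
    scores = as.matrix(sc[, -1, drop = FALSE]),
    ex_loadings = unname(as.matrix(exl[, -1, drop = FALSE])),
    em_loadings = unname(as.matrix(eml[, -1, drop = FALSE])),
    explained_variance = meta$explained_variance,
    iterations = meta$iterations, converged = meta$converged,
    sse = meta$sse, sse_history = meta$sse_history,
    sse_monotone = meta$sse_monotone,
    seed = meta$seed, tol = meta$tol, n_starts = meta$n_starts,
    ridge_rel = meta$ridge_rel, burnin = meta$burnin,
    excitation = exl[[1]], emission = eml[[1]],
    sample_ids = as.character(sc[[1]])
  )
  dimnames(model$scores) <- list(model$sample_ids,
                                 paste0("C", seq_len(model$n_components)))
  structure(model, class = "parafac_model")
}
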