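# FTICR-MS pipeline: CHNOSP molecular-formula assignment of [M-H]- peaks,
# per-sample dynamic range, SDL intensity standardization, and the aligned
# formula x sample intensity matrix.

#' Molecular-formula assignment configuration
#'
#' Default rule set for negative-mode DOM spectra: element bounds C 1-60,
#' H 1-120, N 0-4, O 0-40, S 0-2, P 0-1; 0.3 <= H/C <= 2.5; O/C <= 1.2;
#' integer DBE in \verb{[0, 40]} (the even-electron parity check for
#' \verb{[M-H]-} ions); mass tolerance 0.2 ppm; S/N > 5; singly charged
#' \verb{[M-H]-} assumed throughout. All values overridable.
#'
#' @param tolerance_ppm Mass tolerance in ppm (> 0).
#' @param c_bounds,h_bounds,n_bounds,o_bounds,s_bounds,p_bounds Length-2
#'   integer min/max bounds per element.
#' @param hc,oc H/C bounds and O/C maximum (length-2 / scalar).
#' @param dbe Length-2 DBE bounds.
#' @param integer_dbe Require integer DBE (parity rule); default TRUE.
#' @param snr_min Peaks at or below this signal-to-noise ratio are discarded
#'   at read time.
#' @param mz_range Assignable \verb{[M-H]-} mass window (Da).
#' @return List of class \code{assignment_config}.
#' @export
assignment_config <- function(tolerance_ppm = 0.2,
                              c_bounds = c(1L, 60L), h_bounds = c(1L, 120L),
                              n_bounds = c(0L, 4L), o_bounds = c(0L, 40L),
                              s_bounds = c(0L, 2L), p_bounds = c(0L, 1L),
                              hc = c(0.3, 2.5), oc = 1.2,
                              dbe = c(0, 40), integer_dbe = TRUE,
                              snr_min = 5, mz_range = c(150, 750)) {
  if (tolerance_ppm <= 0) stop("tolerance_ppm must be positive")
  structure(list(tolerance_ppm = tolerance_ppm, c = c_bounds, h = h_bounds,
                 n = n_bounds, o = o_bounds,
                 s = s_bounds, p = p_bounds, hc = hc, oc = oc, dbe = dbe,
                 integer_dbe = integer_dbe, snr_min = snr_min,
                 mz_range = mz_range),
            class = "assignment_config")
}

.db_cache <- new.env(parent = emptyenv())

.cfg_key <- function(cfg) {
  paste(unlist(cfg[c("c", "h", "n", "o", "s", "p", "hc", "oc", "dbe",
                     "integer_dbe", "mz_range")]), collapse = "|")
}

.apply_rules <- function(d, cfg) {
  keep <- d$h / d$c >= cfg$hc[1] & d$h / d$c <= cfg$hc[2] &
    d$o / d$c <= cfg$oc
  db <- 1 + d$c - d$h / 2 + d$n / 2 + d$p / 2
  keep <- keep & db >= cfg$dbe[1] & db <= cfg$dbe[2]
  if (cfg$integer_dbe) keep <- keep & (d$h + d$n + d$p) %% 2 == 0
  keep
}

#' Enumerate the CHNOSP formula database for a rule set
#'
#' Builds the sorted table of every formula within the configured element
#' bounds and chemical rules whose \verb{[M-H]-} mass falls in the assignable
#' window. The optimized assigner queries this table by binary search. The
#' table is cached per rule set within a session.
#'
#' @param cfg An [assignment_config].
#' @return Data frame with columns \code{c,h,n,o,s,p,neutral_mass,ion_mz},
#'   sorted by \code{ion_mz}.
#' @export
build_formula_db <- function(cfg = assignment_config()) {
  key <- .cfg_key(cfg)
  if (!is.null(.db_cache[[key]])) return(.db_cache[[key]])
  lo_mass <- cfg$mz_range[1] - 1
  hi_mass <- cfg$mz_range[2] + 1
  chunks <- vector("list", cfg$c[2])
  for (cc in seq(cfg$c[1], cfg$c[2])) {
    h_lo <- max(cfg$h[1], ceiling(cfg$hc[1] * cc))
    h_hi <- min(cfg$h[2], floor(cfg$hc[2] * cc))
    if (h_lo > h_hi) next
    o_hi <- min(cfg$o[2], floor(cfg$oc * cc))
    g <- expand.grid(h = h_lo:h_hi, n = cfg$n[1]:cfg$n[2],
                     o = cfg$o[1]:o_hi, s = cfg$s[1]:cfg$s[2],
                     p = cfg$p[1]:cfg$p[2], KEEP.OUT.ATTRS = FALSE)
    g$c <- cc
    mass <- monoisotopic_mass(g)
    sel <- mass - PROTON_MASS >= lo_mass & mass - PROTON_MASS <= hi_mass
    g <- g[sel, , drop = FALSE]
    if (nrow(g) == 0) next
    g <- g[.apply_rules(g, cfg), , drop = FALSE]
    if (nrow(g) == 0) next
    g$neutral_mass <- monoisotopic_mass(g)
    chunks[[cc]] <- g[c("c", "h", "n", "o", "s", "p", "neutral_mass")]
  }
  db <- do.call(rbind, chunks[!vapply(chunks, is.null, logical(1))])
  db$ion_mz <- db$neutral_mass - PROTON_MASS
  db <- db[order(db$ion_mz), ]
  rownames(db) <- NULL
  .db_cache[[key]] <- db
  db
}

#' Assign molecular formulae to measured ion masses
#'
#' For each \verb{[M-H]-} mass, finds every database formula within the ppm
#' tolerance. When multiple candidates survive, the lowest absolute ppm error
#' wins, ties broken by fewest heteroatoms (N+S+P), and the peak is flagged
#' ambiguous. Masses outside the assignable window are skipped (counted, not
#' errors).
#'
#' @param mz Numeric vector of measured \verb{[M-H]-} masses (Da).
#' @param cfg An [assignment_config].
#' @param db Optional prebuilt [build_formula_db()] table.
#' @return Data frame, one row per input mass: \code{mz, assigned, c,h,n,o,s,p,
#'   formula, error_ppm, n_candidates, ambiguous, in_range}.
#' @export
assign_formulas <- function(mz, cfg = assignment_config(), db = NULL) {
  if (is.null(db)) db <- build_formula_db(cfg)
  nq <- length(mz)
  out <- data.frame(mz = mz, assigned = FALSE,
                    c = NA_integer_, h = NA_integer_, n = NA_integer_,
                    o = NA_integer_, s = NA_integer_, p = NA_integer_,
                    formula = NA_character_, error_ppm = NA_real_,
                    n_candidates = 0L, ambiguous = FALSE,
                    in_range = mz >= cfg$mz_range[1] & mz <= cfg$mz_range[2])
  delta <- mz * cfg$tolerance_ppm * 1e-6
  first <- findInterval(mz - delta - 1e-12, db$ion_mz) + 1L
  last <- findInterval(mz + delta + 1e-12, db$ion_mz)
  cnt <- pmax(last - first + 1L, 0L)
  cnt[!out$in_range] <- 0L
  out$n_candidates <- cnt
  pick <- integer(nq)
  single <- which(cnt == 1L)
  pick[single] <- first[single]
  for (q in which(cnt > 1L)) {
    idx <- first[q]:last[q]
    err <- abs(db$ion_mz[idx] - mz[q]) / mz[q] * 1e6
    best <- which(err == min(err))
    if (length(best) > 1) {
      het <- db$n[idx[best]] + db$s[idx[best]] + db$p[idx[best]]
      best <- best[which.min(het)]
    }
    pick[q] <- idx[best[1]]
  }
  hit <- which(pick > 0)
  if (length(hit)) {
    sel <- pick[hit]
    for (el in c("c", "h", "n", "o", "s", "p")) out[[el]][hit] <- db[[el]][sel]
    out$formula[hit] <- format_formula(db[sel, ])
    out$error_ppm[hit] <- (mz[hit] - db$ion_mz[sel]) / db$ion_mz[sel] * 1e6
    out$assigned[hit] <- TRUE
    out$ambiguous[hit] <- cnt[hit] > 1L
  }
  out
}

.bf_cache <- new.env(parent = emptyenv())

#' Brute-force reference formula assigner
#'
#' Independent enumeration oracle: scans the full CHNOSP grid within the
#' element bounds (no mass index, no per-carbon pruning), keeps every
#' combination whose \verb{[M-H]-} mass lies within tolerance, applies the
#' chemical rules to the survivors, and picks the winner by the same
#' lowest-|ppm| / fewest-heteroatoms rule. Used to cross-check the optimized
#' assigner; far too slow for production use.
#'
#' @param mz A single measured \verb{[M-H]-} mass (Da).
#' @param cfg An [assignment_config].
#' @return One-row data frame in the [assign_formulas()] layout.
#' @export
assign_formula_bruteforce <- function(mz, cfg = assignment_config()) {
  key <- paste(unlist(cfg[c("c", "h", "n", "o", "s", "p")]), collapse = "|")
  grid <- .bf_cache[[key]]
  if (is.null(grid)) {
    grid <- expand.grid(c = cfg$c[1]:cfg$c[2], h = cfg$h[1]:cfg$h[2],
                        n = cfg$n[1]:cfg$n[2], o = cfg$o[1]:cfg$o[2],
                        s = cfg$s[1]:cfg$s[2], p = cfg$p[1]:cfg$p[2],
                        KEEP.OUT.ATTRS = FALSE)
    grid$ion_mz <- monoisotopic_mass(grid) - PROTON_MASS
    .bf_cache[[key]] <- grid
  }
  out <- data.frame(mz = mz, assigned = FALSE,
                    c = NA_integer_, h = NA_integer_, n = NA_integer_,
                    o = NA_integer_, s = NA_integer_, p = NA_integer_,
                    formula = NA_character_, error_ppm = NA_real_,
                    n_candidates = 0L, ambiguous = FALSE,
                    in_range = mz >= cfg$mz_range[1] & mz <= cfg$mz_range[2])
  if (!out$in_range) return(out)
  tol <- mz * cfg$tolerance_ppm * 1e-6
  cand <- grid[abs(grid$ion_mz - mz) <= tol + 1e-12, , drop = FALSE]
  if (nrow(cand)) cand <- cand[.apply_rules(cand, cfg), , drop = FALSE]
  if (nrow(cand) == 0) return(out)
  err <- abs(cand$ion_mz - mz) / mz * 1e6
  best <- which(err == min(err))
  if (length(best) > 1) {
    best <- best[which.min(cand$n[best] + cand$s[best] + cand$p[best])]
  }
  b <- cand[best[1], ]
  out$assigned <- TRUE
  for (el in c("c", "h", "n", "o", "s", "p")) out[[el]] <- b[[el]]
  out$formula <- format_formula(b)
  out$error_ppm <- (mz - b$ion_mz) / b$ion_mz * 1e6
  out$n_candidates <- nrow(cand)
  out$ambiguous <- nrow(cand) > 1
  out
}

#' Dynamic range of a peak list
#'
#' Mean intensity of the highest \code{min(500, n)} peaks divided by the
#' signal-to-noise threshold intensity (mean of the 10 lowest peaks).
#'
#' @param intensities Numeric vector of peak intensities (>= 10 values).
#' @export
dynamic_range <- function(intensities) {
  n <- length(intensities)
  if (n < 10) stop("dynamic range needs at least 10 peaks")
  srt <- sort(intensities, decreasing = TRUE)
  mean(srt[seq_len(min(500, n))]) / mean(srt[(n - 9):n])
}

#' SDL standardization of per-sample formula intensities
#'
#' The cohort's lowest dynamic range (DR) defines each sample's standardized
#' detection limit: \code{SDL_s = mean(top-500 intensities of s) / min DR}.
#' Rows are the union of formulae assigned in any sample; for each sample,
#' any union formula not detected there, or detected below the sample's SDL,
#' is set to that sample's SDL (false-negative prevention across samples);
#' detected intensities at or above the SDL pass through unchanged.
#'
#' @param formula_intensities List (one element per sample) of named numeric
#'   vectors: detected intensity per assigned formula string.
#' @param peak_intensities List (same order) of the full post-S/N-filter peak
#'   intensity vectors used for DR and SDL.
#' @param sample_ids Sample identifiers.
#' @return List with \code{intensities} (formula x sample matrix after SDL
#'   fill), \code{sdl} and \code{dr} per sample, and \code{formulae}.
#' @export
sdl_standardize <- function(formula_intensities, peak_intensities,
                            sample_ids = names(formula_intensities)) {
  ns <- length(formula_intensities)
  if (ns < 2) stop("need at least 2 samples")
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(ns))
  dr <- vapply(peak_intensities, dynamic_range, numeric(1))
  topmean <- vapply(peak_intensities, function(v) {
    mean(sort(v, decreasing = TRUE)[seq_len(min(500, length(v)))])
  }, numeric(1))
  sdl <- topmean / min(dr)
  formulae <- sort(unique(unlist(lapply(formula_intensities, names))))
  m <- matrix(NA_real_, length(formulae), ns,
              dimnames = list(formulae, sample_ids))
  for (j in seq_len(ns)) {
    v <- formula_intensities[[j]]
    m[, j] <- sdl[j]
    if (length(v)) {
      idx <- match(names(v), formulae)
      m[idx, j] <- pmax(v, sdl[j])
    }
  }
  list(intensities = m, sdl = stats::setNames(sdl, sample_ids),
       dr = stats::setNames(dr, sample_ids), formulae = formulae)
}

#' Column-stochastic normalization of an intensity matrix
#'
#' Divides each sample column by its total so columns sum to 1. All-zero
#' columns are dropped with a message.
#'
#' @param m Numeric matrix (formula x sample).
#' @return Normalized matrix.
#' @export
normalize_columns <- function(m) {
  tot <- colSums(m)
  if (any(tot <= 0)) {
    message("dropping zero-total sample column(s): ",
            paste(colnames(m)[tot <= 0], collapse = ", "))
    m <- m[, tot > 0, drop = FALSE]
    tot <- tot[tot > 0]
  }
  sweep(m, 2, tot, `/`)
}

#' Build the annotated formula x sample peak matrix from peak lists
#'
#' End-to-end FTICR stage: filters peaks at the configured S/N threshold,
#' assigns CHNOSP formulae (winner-only; ambiguous assignments are kept and
#' flagged), aggregates duplicate formula hits within a sample by maximum
#' intensity, standardizes detection limits across samples (DR/SDL), and
#' normalizes each sample column to unit total intensity.
#'
#' @param peaklists List (per sample) of data frames with columns
#'   \code{mz, intensity, snr}.
#' @param sample_ids Sample identifiers.
#' @param cfg An [assignment_config].
#' @param db Optional prebuilt formula database.
#' @return Object of class \code{peak_matrix}: \code{annotations} (one row per
#'   union formula, via [annotate_formulae()], plus an \code{ambiguous} flag),
#'   \code{intensities}, \code{normalized}, \code{sdl}, \code{dr},
#'   \code{samples}, and per-sample assignment counts.
#' @export
peak_matrix <- function(peaklists, sample_ids = names(peaklists),
                        cfg = assignment_config(), db = NULL) {
  if (is.null(db)) db <- build_formula_db(cfg)
  ns <- length(peaklists)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(ns))
  formula_int <- vector("list", ns)
  peak_int <- vector("list", ns)
  counts <- data.frame(sample_id = sample_ids, n_peaks = 0L, n_snr_pass = 0L,
                       n_assigned = 0L, n_ambiguous = 0L, n_out_of_range = 0L)
  ambiguous_formulae <- character(0)
  for (j in seq_len(ns)) {
    pl <- peaklists[[j]]
    counts$n_peaks[j] <- nrow(pl)
    pl <- pl[pl$snr > cfg$snr_min, , drop = FALSE]
    counts$n_snr_pass[j] <- nrow(pl)
    peak_int[[j]] <- pl$intensity
    asg <- assign_formulas(pl$mz, cfg, db)
    counts$n_assigned[j] <- sum(asg$assigned)
    counts$n_ambiguous[j] <- sum(asg$ambiguous)
    counts$n_out_of_range[j] <- sum(!asg$in_range)
    ok <- asg$assigned
    ambiguous_formulae <- union(ambiguous_formulae, asg$formula[ok & asg$ambiguous])
    agg <- tapply(pl$intensity[ok], asg$formula[ok], max)
    formula_int[[j]] <- stats::setNames(as.numeric(agg), names(agg))
  }
  std <- sdl_standardize(formula_int, peak_int, sample_ids)
  ann <- annotate_formulae(std$formulae)
  ann$ambiguous <- ann$formula %in% ambiguous_formulae
  structure(list(annotations = ann,
                 samples = sample_ids,
                 intensities = std$intensities,
                 normalized = normalize_columns(std$intensities),
                 sdl = std$sdl, dr = std$dr,
                 assignment_counts = counts,
                 config = cfg),
            class = "peak_matrix")
}

#' @export
print.peak_matrix <- function(x, ...) {
  cat(sprintf("peak matrix: %d formulae x %d samples (DR %.1f-%.1f)\n",
              nrow(x$intensities), length(x$samples),
              min(x$dr), max(x$dr)))
  invisible(x)
}

#' Read a per-sample peak-list CSV
#'
#' Dialect: columns \code{mz, intensity, snr}; no filtering is applied here
#' (the S/N threshold is applied by [peak_matrix()]).
#'
#' @param path File path.
#' @export
read_peaklist_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")[c("mz", "intensity", "snr")]
}
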