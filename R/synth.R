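# Synthetic cohort generator: EEMs with trilinear components plus Rayleigh
# scatter, matched blanks, exponential absorbance spectra, DOC, and FTICR
# peak lists with Gaussian-copula links between formula intensities and
# optical drivers. Every generated quantity is recorded in a machine-readable
# ground-truth manifest so each pipeline stage has a recoverable truth.

#' Generator configuration
#'
#' Defaults emulate the study cohort: 57 samples, 4 fluorescent components
#' with excitation/emission maxima placed near the reported component peaks,
#' the instrument grids (excitation 260-455 nm step 5, emission 250-704 nm
#' step 2, scanned from ex+10 to ex+250), absorbance 250-800 nm on a 1-cm
#' cell with indices spanning the reported envelopes (a254 10-204 m^-1,
#' SUVA254 0.7-4.9, DOC 3.3-20.4 mg-C L^-1), 3000 formulae over 150-750 Da
#' with class mixture near the reported composition, 1%-of-maximum Gaussian
#' EEM noise, and Gaussian-copula plants tying chosen formulae to chosen
#' optical drivers at stated population Spearman rho.
#'
#' @param n_samples Number of samples.
#' @param ex_grid,em_grid Instrument wavelength grids (nm).
#' @param component_ex,component_em,component_ex_width,component_em_width
#'   Per-component excitation peak positions (list), emission peak, and
#'   Gaussian widths (nm).
#' @param score_meanlog,score_sdlog Log-normal per-sample component scores;
#'   the decreasing means plant the component abundance ordering.
#' @param noise_level EEM noise s.d. as a fraction of each sample's maximum.
#' @param scatter_amplitude First-order Rayleigh ridge amplitude as a fraction
#'   of the sample maximum (second order gets half); widths in nm.
#' @param blank_level Blank offset as a fraction of the median sample maximum.
#' @param abs_wavelengths,path_length Absorbance grid (nm) and path (m).
#' @param a254_range,s275_range,s350_range,suva_range,doc_range Sampling
#'   envelopes for the absorbance truth (Napierian a254 m^-1, slopes nm^-1,
#'   SUVA L mg-C^-1 m^-1, DOC mg-C L^-1).
#' @param n_formulae Library size; drawn from the assignable CHNOSP database.
#' @param class_weights Named sampling weights over compound classes.
#' @param intensity_meanlog_sd,intensity_sdlog Between-formula spread of
#'   log-mean intensity and within-formula across-sample log-s.d.
#' @param mz_jitter_ppm Uniform mass perturbation half-width (ppm).
#' @param snr_range Signal-to-noise range for detectable peaks.
#' @param low_snr_prob Probability a (formula, sample) peak falls at or below
#'   the S/N threshold (and is therefore dropped at read time).
#' @param n_noise_peaks Unassignable low-intensity peaks added per sample.
#' @param plant_drivers,plant_rhos Drivers receiving plants and the population
#'   Spearman rho values planted per driver (negative = inverse link).
#' @param n_overlap,overlap_pair,overlap_rho A set of formulae planted jointly
#'   on two drivers (shared-formula truth).
#' @return List of class \code{generator_config}.
#' @export
generator_config <- function(
    n_samples = 57,
    ex_grid = seq(260, 455, by = 5),
    em_grid = seq(250, 704, by = 2),
    component_ex = list(c(260, 310), c(260, 370), c(260, 300), 275),
    component_em = c(425, 505, 375, 320),
    component_ex_width = c(40, 25, 20, 18),
    component_em_width = c(45, 50, 40, 28),
    score_meanlog = log(c(1.25, 0.6, 0.45, 0.3)),
    score_sdlog = 0.35,
    noise_level = 0.01,
    scatter_amplitude = 0.3,
    scatter_widths = c(5, 7),
    blank_level = 0.004,
    abs_wavelengths = seq(250, 800, by = 1),
    path_length = 0.01,
    a254_range = c(10, 204),
    s275_range = c(0.016, 0.034),
    s350_range = c(0.008, 0.030),
    suva_range = c(0.7, 4.9),
    doc_range = c(3.3, 20.4),
    n_formulae = 3000,
    class_weights = c(highly_unsaturated = 0.545, polyphenol = 0.17,
                      unsaturated_aliphatic = 0.135, black_carbon = 0.087,
                      peptide = 0.041, saturated_fatty_acid = 0.015,
                      sugar = 0.007),
    intensity_meanlog_sd = 1,
    intensity_sdlog = 0.7,
    mz_jitter_ppm = 0.1,
    snr_range = c(6, 150),
    low_snr_prob = 0.03,
    n_noise_peaks = 300,
    plant_drivers = c("c1", "c2", "c3", "c4", "suva254", "fi"),
    plant_rhos = rep(c(0.9, 0.8, 0.7, 0.6, -0.8), times = 8),
    n_overlap = 30, overlap_pair = c("c3", "c4"), overlap_rho = 0.8) {
  cfg <- as.list(environment())
  if (cfg$n_samples < 2) stop("n_samples must be >= 2")
  if (any(cfg$class_weights < 0)) stop("class weights must be non-negative")
  structure(cfg, class = "generator_config")
}

.gauss_bumps <- function(grid, centers, width) {
  v <- rowSums(vapply(centers, function(mu) exp(-(grid - mu)^2 / (2 * width^2)),
                      numeric(length(grid))))
  v / max(v)
}

# Latent standard-normal transform of a driver's realized values.
.rank_latent <- function(x) stats::qnorm((rank(x) - 0.5) / length(x))

# Pearson correlation of the Gaussian latents that yields a given population
# Spearman rho under a Gaussian copula.
.latent_r <- function(rho_s) 2 * sin(pi * rho_s / 6)

#' Generate a synthetic cohort with ground-truth manifest
#'
#' Draws component loadings (Gaussian bumps at the configured peak
#' positions), log-normal per-sample scores with a planted abundance
#' ordering, trilinear EEMs plus first/second-order Rayleigh ridges,
#' inner-filter attenuation consistent with each sample's absorbance
#' spectrum, matched near-zero blanks, piecewise-exponential absorbance with
#' planted spectral slopes, and FTICR peak lists in which chosen formulae are
#' tied to chosen optical drivers through Gaussian copulas at stated
#' population Spearman rho (exact \verb{[M-H]-} masses perturbed by at most
#' \code{mz_jitter_ppm}).
#'
#' @param cfg A [generator_config()].
#' @param seed Integer seed; identical \code{(cfg, seed)} reproduce the cohort
#'   exactly.
#' @return List of class \code{dom_cohort}: \code{samples} (manifest data
#'   frame), \code{absorbance}, \code{eems}, \code{blanks}, \code{peaklists}
#'   (per-sample lists), and \code{manifest} (the truth).
#' @export
generate_cohort <- function(cfg = generator_config(), seed = 1) {
  set.seed(seed)
  ns <- cfg$n_samples
  ex <- cfg$ex_grid; em <- cfg$em_grid
  k <- length(cfg$component_em)
  sample_ids <- sprintf("S%02d", seq_len(ns))

  # --- component loadings and scores ---------------------------------------
  B <- vapply(seq_len(k), function(r) {
    .gauss_bumps(ex, cfg$component_ex[[r]], cfg$component_ex_width[r])
  }, numeric(length(ex)))
  C <- vapply(seq_len(k), function(r) {
    .gauss_bumps(em, cfg$component_em[r], cfg$component_em_width[r])
  }, numeric(length(em)))
  A <- vapply(seq_len(k), function(r) {
    stats::rlnorm(ns, cfg$score_meanlog[r], cfg$score_sdlog)
  }, numeric(ns))
  dimnames(A) <- list(sample_ids, paste0("c", seq_len(k)))

  # --- absorbance truth ----------------------------------------------------
  a254 <- exp(stats::runif(ns, log(cfg$a254_range[1]), log(cfg$a254_range[2])))
  s275 <- stats::runif(ns, cfg$s275_range[1], cfg$s275_range[2])
  s350 <- stats::runif(ns, cfg$s350_range[1], cfg$s350_range[2])
  suva_target <- stats::runif(ns, cfg$suva_range[1], cfg$suva_range[2])
  doc <- pmin(pmax(a254 / log(10) / suva_target, cfg$doc_range[1]),
              cfg$doc_range[2])
  lam <- cfg$abs_wavelengths
  break_nm <- 315
  absorbance <- vector("list", ns)
  for (i in seq_len(ns)) {
    # piecewise log-linear Napierian coefficient: slope s275 below the break,
    # s350 above, continuous at the break, anchored at a254(254 nm)
    ln_a <- ifelse(lam <= break_nm,
                   log(a254[i]) - s275[i] * (lam - 254),
                   log(a254[i]) - s275[i] * (break_nm - 254) -
                     s350[i] * (lam - break_nm))
    A_dec <- exp(ln_a) * cfg$path_length / log(10)
    absorbance[[i]] <- absorbance_spectrum(lam, A_dec, cfg$path_length)
  }

  # --- EEMs ----------------------------------------------------------------
  ragged <- outer(ex, em, function(e, m) m < e + 10 | m > e + 250)
  d1 <- outer(ex, em, function(e, m) m - e)
  d2 <- outer(ex, em, function(e, m) m - 2 * e)
  eems <- vector("list", ns)
  blanks <- vector("list", ns)
  slab_max <- numeric(ns)
  for (i in seq_len(ns)) {
    true_slab <- matrix(0, length(ex), length(em))
    for (r in seq_len(k)) true_slab <- true_slab + A[i, r] * outer(B[, r], C[, r])
    mx <- max(true_slab)
    slab_max[i] <- mx
    scat <- cfg$scatter_amplitude * mx *
      (exp(-d1^2 / (2 * cfg$scatter_widths[1]^2)) +
         0.5 * exp(-d2^2 / (2 * cfg$scatter_widths[2]^2)))
    spec <- absorbance[[i]]
    path_cm <- spec$path_length * 100
    a_ex <- .abs_at(spec, ex) / path_cm
    a_em <- .abs_at(spec, em) / path_cm
    atten <- 10^(-outer(a_ex, a_em, `+`) / 2)
    bl <- cfg$blank_level * mx
    obs <- (true_slab + scat) * atten + bl +
      matrix(stats::rnorm(length(ex) * length(em), 0, cfg$noise_level * mx),
             length(ex), length(em))
    blank_slab <- bl +
      matrix(stats::rnorm(length(ex) * length(em), 0,
                          0.2 * cfg$noise_level * mx),
             length(ex), length(em))
    eems[[i]] <- eem(ex, em, obs, mask = ragged, units_tag = "raw")
    blanks[[i]] <- eem(ex, em, blank_slab, mask = ragged, units_tag = "raw")
  }
  names(eems) <- names(blanks) <- sample_ids

  # --- closed-form optical truth -------------------------------------------
  frac <- A / rowSums(A)
  em_at <- function(target) vapply(seq_len(k), function(r) {
    stats::approx(em, C[, r], xout = target)$y
  }, numeric(1))
  ex_at <- function(target) vapply(seq_len(k), function(r) {
    stats::approx(ex, B[, r], xout = target)$y
  }, numeric(1))
  intensity_at <- function(ex_t, em_t) {
    as.numeric(A %*% (ex_at(ex_t) * em_at(em_t)))
  }
  fi_true <- intensity_at(370, 470) / intensity_at(370, 520)
  fresh_win <- em[em >= 420 & em <= 435]
  fresh_den <- apply(vapply(fresh_win, function(w) intensity_at(310, w),
                            numeric(ns)), 1, max)
  fresh_true <- intensity_at(310, 380) / fresh_den
  ex_hix <- min(ex)
  row_int <- function(lo, hi) {
    # trapezoid on the emission grid with interpolated endpoints, matching
    # the index pipeline exactly
    ems <- sort(unique(c(lo, hi, em[em >= lo & em <= hi])))
    vals <- vapply(ems, function(w) intensity_at(ex_hix, w), numeric(ns))
    apply(vals, 1, function(v) pracma::trapz(ems, v))
  }
  h_area <- row_int(435, 480)
  l_area <- row_int(300, 345)
  optics_true <- data.frame(
    sample_id = sample_ids, frac,
    a254 = a254,
    suva254 = a254 / log(10) / doc,
    s275_295 = s275, s350_400 = s350, s_r = s275 / s350,
    fi = fi_true, freshness = fresh_true,
    hix = h_area / l_area, hix_ohno = h_area / (h_area + l_area),
    row.names = NULL
  )

  # --- formula library and planted links -----------------------------------
  db <- build_formula_db(assignment_config())
  # keep the library strictly inside the assignable window (jitter-safe)
  db <- db[db$ion_mz > 150.001 & db$ion_mz < 749.999, ]
  db_class <- classify_formula(db)
  wts <- cfg$class_weights[db_class]
  wts[is.na(wts)] <- 0
  lib_idx <- sample.int(nrow(db), cfg$n_formulae, prob = wts)
  lib <- annotate_formulae(db[lib_idx, c("c", "h", "n", "o", "s", "p")])
  rownames(lib) <- NULL
  lib$meanlog <- stats::rnorm(cfg$n_formulae, log(1e7), cfg$intensity_meanlog_sd)
  lib$planted_driver <- NA_character_
  lib$planted_rho <- NA_real_
  lib$overlap_plant <- FALSE

  n_plant_per <- length(cfg$plant_rhos)
  n_plants <- length(cfg$plant_drivers) * n_plant_per + cfg$n_overlap
  if (n_plants > cfg$n_formulae) stop("more plants than formulae")
  plant_idx <- sample.int(cfg$n_formulae, n_plants)
  pos <- 0
  for (d in cfg$plant_drivers) {
    idx <- plant_idx[pos + seq_len(n_plant_per)]
    lib$planted_driver[idx] <- d
    lib$planted_rho[idx] <- cfg$plant_rhos
    pos <- pos + n_plant_per
  }
  if (cfg$n_overlap > 0) {
    idx <- plant_idx[pos + seq_len(cfg$n_overlap)]
    lib$planted_driver[idx] <- paste(cfg$overlap_pair, collapse = "+")
    lib$planted_rho[idx] <- cfg$overlap_rho
    lib$overlap_plant[idx] <- TRUE
  }

  drivers <- optics_true
  latents <- list(
    c1 = .rank_latent(drivers$c1), c2 = .rank_latent(drivers$c2),
    c3 = .rank_latent(drivers$c3), c4 = .rank_latent(drivers$c4),
    a254 = .rank_latent(drivers$a254), suva254 = .rank_latent(drivers$suva254),
    s275_295 = .rank_latent(drivers$s275_295),
    s350_400 = .rank_latent(drivers$s350_400),
    s_r = .rank_latent(drivers$s_r),
    fi = .rank_latent(drivers$fi), freshness = .rank_latent(drivers$freshness),
    hix = .rank_latent(drivers$hix)
  )
  z12 <- latents[[cfg$overlap_pair[1]]] + latents[[cfg$overlap_pair[2]]]
  latents[[paste(cfg$overlap_pair, collapse = "+")]] <- z12 / sqrt(sum(z12^2) / ns)

  intens <- matrix(0, cfg$n_formulae, ns, dimnames = list(lib$formula, sample_ids))
  for (j in seq_len(cfg$n_formulae)) {
    if (is.na(lib$planted_driver[j])) {
      intens[j, ] <- stats::rlnorm(ns, lib$meanlog[j], cfg$intensity_sdlog)
    } else {
      r <- .latent_r(abs(lib$planted_rho[j])) * sign(lib$planted_rho[j])
      z <- r * latents[[lib$planted_driver[j]]] +
        sqrt(1 - r^2) * stats::rnorm(ns)
      intens[j, ] <- stats::qlnorm(stats::pnorm(z), lib$meanlog[j],
                                   cfg$intensity_sdlog)
    }
  }

  # --- peak lists ----------------------------------------------------------
  peaklists <- vector("list", ns)
  for (i in seq_len(ns)) {
    jit <- stats::runif(cfg$n_formulae, -cfg$mz_jitter_ppm, cfg$mz_jitter_ppm)
    mz <- lib$ion_mz * (1 + jit * 1e-6)
    snr <- stats::runif(cfg$n_formulae, cfg$snr_range[1], cfg$snr_range[2])
    low <- stats::runif(cfg$n_formulae) < cfg$low_snr_prob
    snr[low] <- stats::runif(sum(low), 1, 5)
    noise_mz <- stats::runif(cfg$n_noise_peaks, 150, 750)
    noise_int <- stats::rlnorm(cfg$n_noise_peaks, log(2e5), 0.6)
    noise_snr <- stats::runif(cfg$n_noise_peaks, 5.5, 30)
    pl <- data.frame(
      mz = c(mz, noise_mz),
      intensity = c(intens[, i], noise_int),
      snr = c(snr, noise_snr)
    )
    peaklists[[i]] <- pl[order(pl$mz), ]
    rownames(peaklists[[i]]) <- NULL
  }
  names(peaklists) <- sample_ids

  samples <- data.frame(sample_id = sample_ids, doc_mg_per_l = doc,
                        path_length_m = cfg$path_length,
                        salinity = round(stats::runif(ns, 0, 40), 1),
                        parafac_fit = TRUE, screen = TRUE)

  manifest <- structure(list(
    seed = seed,
    config = unclass(cfg),
    ex_loadings = B, em_loadings = C, scores = A,
    absorbance_params = data.frame(sample_id = sample_ids, a254 = a254,
                                   s275 = s275, s350 = s350, doc = doc),
    optics_true = optics_true,
    formulas = lib,
    slab_max = stats::setNames(slab_max, sample_ids)
  ), class = "truth_manifest")

  structure(list(samples = samples, absorbance = absorbance, eems = eems,
                 blanks = blanks, peaklists = peaklists, manifest = manifest),
            class = "dom_cohort")
}

#' @export
print.dom_cohort <- function(x, ...) {
  cat(sprintf("synthetic DOM cohort: %d samples, %d formulae, %d components\n",
              nrow(x$samples), nrow(x$manifest$formulas),
              ncol(x$manifest$scores)))
  invisible(x)
}

#' Analytic power of the Spearman screen
#'
#' Normal approximation through the Fisher z-transform of the Gaussian-copula
#' latent correlation, with the Fieller variance inflation for rank
#' correlation (variance 1.06/(n-3)).
#'
#' @param rho_s Population Spearman rho (may be negative).
#' @param n Sample size.
#' @param alpha Two-sided significance level.
#' @return Detection probability.
#' @export
spearman_power <- function(rho_s, n, alpha = 0.01) {
  r <- .latent_r(abs(rho_s))
  se <- sqrt(1.06 / (n - 3))
  stats::pnorm(abs(atanh(r)) / se - stats::qnorm(1 - alpha / 2))
}

#' Expected pipeline outputs from a truth manifest alone
#'
#' Computes, without re-running the generator or the pipeline, the expected
#' positively/negatively significant formula sets per driver (plants whose
#' analytic detection power exceeds \code{power_threshold}), the expected
#' class-summary counts of those sets, and the expected shared-formula
#' overlap of the jointly planted pair.
#'
#' @param manifest A \code{truth_manifest}.
#' @param alpha Screen significance level.
#' @param power_threshold Minimum [spearman_power()] for a plant to be
#'   counted as expected-detected. The default 0.999 counts plants at
#'   population rho >= 0.7 and leaves weaker plants out of the expected
#'   tables: their analytic power is high on the true drivers but the
#'   pipeline screens against estimated drivers and SDL-standardized
#'   intensities, which attenuates marginal links.
#' @return List with \code{expected_positive}, \code{expected_negative}
#'   (named lists of formula vectors), \code{expected_class_counts} (data
#'   frame), \code{plants} (the planted table with power), and
#'   \code{expected_overlap}.
#' @export
expected_outputs <- function(manifest, alpha = 0.01, power_threshold = 0.999) {
  lib <- manifest$formulas
  n <- nrow(manifest$optics_true)
  plants <- lib[!is.na(lib$planted_driver), ]
  plants$power <- spearman_power(plants$planted_rho, n, alpha)
  detected <- plants[plants$power >= power_threshold, ]
  drivers <- unique(detected$planted_driver[!detected$overlap_plant])
  pos <- lapply(drivers, function(d) {
    detected$formula[detected$planted_driver == d & detected$planted_rho > 0]
  })
  neg <- lapply(drivers, function(d) {
    detected$formula[detected$planted_driver == d & detected$planted_rho < 0]
  })
  names(pos) <- names(neg) <- drivers
  cc <- lapply(drivers, function(d) {
    set <- detected[detected$planted_driver == d & detected$planted_rho > 0, ]
    data.frame(driver = d,
               class = COMPOUND_CLASSES,
               n_expected = vapply(COMPOUND_CLASSES, function(cl) {
                 sum(set$compound_class == cl)
               }, integer(1)), row.names = NULL)
  })
  overlap <- detected$formula[detected$overlap_plant]
  list(expected_positive = pos, expected_negative = neg,
       expected_class_counts = do.call(rbind, cc),
       plants = plants, expected_overlap = overlap)
}

#' Write / read a cohort as plain-text files
#'
#' Writes the sample manifest, per-sample absorbance spectra, EEMs, blanks,
#' and peak lists in the package CSV dialects, plus the truth manifest as
#' JSON. [read_cohort()] reconstitutes the cohort.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory.
#' @export
write_cohort <- function(cohort, dir) {
  for (sub in c("absorbance", "eem", "blank", "peaks")) {
    dir.create(file.path(dir, sub), showWarnings = FALSE, recursive = TRUE)
  }
  utils::write.csv(cohort$samples, file.path(dir, "samples.csv"),
                   row.names = FALSE)
  ids <- cohort$samples$sample_id
  for (i in seq_along(ids)) {
    write_absorbance_csv(cohort$absorbance[[i]],
                         file.path(dir, "absorbance", paste0(ids[i], ".csv")))
    write_eem_csv(cohort$eems[[i]],
                  file.path(dir, "eem", paste0(ids[i], ".csv")))
    write_eem_csv(cohort$blanks[[i]],
                  file.path(dir, "blank", paste0(ids[i], ".csv")))
    utils::write.csv(cohort$peaklists[[i]],
                     file.path(dir, "peaks", paste0(ids[i], ".csv")),
                     row.names = FALSE)
  }
  write_manifest(cohort$manifest, file.path(dir, "truth_manifest.json"))
  invisible(dir)
}

#' @param dir Directory written by [write_cohort()].
#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  samples <- utils::read.csv(file.path(dir, "samples.csv"))
  ids <- samples$sample_id
  rd <- function(sub, reader, ...) {
    out <- lapply(ids, function(id) reader(file.path(dir, sub, paste0(id, ".csv")), ...))
    names(out) <- ids
    out
  }
  absorbance <- lapply(seq_along(ids), function(i) {
    read_absorbance_csv(file.path(dir, "absorbance", paste0(ids[i], ".csv")),
                        path_length = samples$path_length_m[i])
  })
  names(absorbance) <- ids
  manifest_path <- file.path(dir, "truth_manifest.json")
  manifest <- if (file.exists(manifest_path)) read_manifest(manifest_path) else NULL
  structure(list(samples = samples,
                 absorbance = absorbance,
                 eems = rd("eem", read_eem_csv),
                 blanks = rd("blank", read_eem_csv),
                 peaklists = rd("peaks", read_peaklist_csv),
                 manifest = manifest),
            class = "dom_cohort")
}

#' Serialize / load a truth manifest (JSON)
#'
#' @param manifest A \code{truth_manifest}.
#' @param path JSON file path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("ex_loadings", "em_loadings", "scores")) m[[f]] <- as.matrix(m[[f]])
  dimnames(m$scores) <- list(m$optics_true$sample_id,
                             paste0("c", seq_len(ncol(m$scores))))
  m$slab_max <- unlist(m$slab_max)
  structure(m, class = "truth_manifest")
}
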