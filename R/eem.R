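# Excitation-emission matrix hygiene (blank subtraction, inner-filter
# correction, Rayleigh-scatter excision, unit scaling) and the scalar
# fluorescence indices FI, freshness, and HIX.

#' Create an excitation-emission matrix (EEM)
#'
#' @param excitation Strictly increasing excitation grid (nm).
#' @param emission Strictly increasing emission grid (nm).
#' @param intensity Matrix (excitation x emission) of fluorescence intensities
#'   in arbitrary units or QSU.
#' @param mask Logical matrix of the same shape; \code{TRUE} marks a missing /
#'   excised cell whose intensity carries no meaning. Defaults to
#'   \code{is.na(intensity)}.
#' @param units_tag One of \code{"raw"}, \code{"blank_subtracted"},
#'   \code{"ife_corrected"}, \code{"qsu"}.
#' @return An object of class \code{eem}.
#' @export
eem <- function(excitation, emission, intensity, mask = NULL,
                units_tag = "raw") {
  intensity <- as.matrix(intensity)
  if (any(diff(excitation) <= 0) || any(diff(emission) <= 0)) {
    stop("excitation and emission grids must be strictly increasing")
  }
  if (!all(dim(intensity) == c(length(excitation), length(emission)))) {
    stop("intensity must be excitation x emission")
  }
  if (is.null(mask)) mask <- is.na(intensity)
  mask <- as.matrix(mask) | is.na(intensity)
  if (!all(dim(mask) == dim(intensity))) stop("mask and intensity shapes differ")
  intensity[mask] <- NA_real_
  structure(list(excitation = as.numeric(excitation),
                 emission = as.numeric(emission),
                 intensity = intensity, mask = mask,
                 units_tag = units_tag),
            class = "eem")
}

#' @export
print.eem <- function(x, ...) {
  cat(sprintf("EEM: %d ex (%.0f-%.0f nm) x %d em (%.0f-%.0f nm), %s, %.1f%% masked\n",
              length(x$excitation), min(x$excitation), max(x$excitation),
              length(x$emission), min(x$emission), max(x$emission),
              x$units_tag, 100 * mean(x$mask)))
  invisible(x)
}

.check_same_grids <- function(a, b) {
  if (!isTRUE(all.equal(a$excitation, b$excitation)) ||
      !isTRUE(all.equal(a$emission, b$emission))) {
    stop("EEM grids do not match")
  }
}

#' Blank subtraction
#'
#' Cellwise difference of a sample EEM and a matched blank; negative results
#' are floored at 0. Grids must be identical; the union of both masks is kept.
#'
#' @param sample,blank [eem] objects on identical grids.
#' @return Blank-subtracted [eem].
#' @export
blank_subtract <- function(sample, blank) {
  .check_same_grids(sample, blank)
  v <- pmax(sample$intensity - blank$intensity, 0)
  eem(sample$excitation, sample$emission, v,
      mask = sample$mask | blank$mask, units_tag = "blank_subtracted")
}

#' Inner-filter effect correction (absorbance-based)
#'
#' ABA correction: \eqn{F_{corr}(\lambda_{ex}, \lambda_{em}) = F_{obs} \times
#' 10^{(A_{ex} + A_{em})/2}} with A the decadic absorbance over a 1-cm path,
#' derived from the sample's absorbance spectrum. Cells where
#' \eqn{A_{ex} + A_{em} > 3} are corrected anyway but trigger a warning
#' (the correction is unreliable at such opacity).
#'
#' @param x An [eem].
#' @param spec An [absorbance_spectrum] covering every excitation and emission
#'   wavelength of the EEM.
#' @return Corrected [eem].
#' @export
inner_filter_correct <- function(x, spec) {
  rng <- range(spec$wavelengths)
  waves <- c(x$excitation, x$emission)
  if (any(waves < rng[1] | waves > rng[2])) {
    stop("absorbance spectrum does not cover the EEM wavelength range")
  }
  path_cm <- spec$path_length * 100
  a_ex <- .abs_at(spec, x$excitation) / path_cm  # decadic absorbance per cm
  a_em <- .abs_at(spec, x$emission) / path_cm
  total <- outer(a_ex, a_em, `+`)
  if (any(total[!x$mask] > 3)) {
    warning("A_ex + A_em > 3 in ", sum(total[!x$mask] > 3),
            " cells; inner-filter correction unreliable there")
  }
  eem(x$excitation, x$emission, x$intensity * 10^(total / 2),
      mask = x$mask, units_tag = "ife_corrected")
}

#' Excise first- and second-order Rayleigh scatter
#'
#' Masks cells with \code{|em - ex| <= first_width} or
#' \code{|em - 2 ex| <= second_width}. Excised cells are left missing, not
#' interpolated (interpolation would fabricate trilinear structure for the
#' downstream PARAFAC fit). Idempotent.
#'
#' @param x An [eem].
#' @param first_width,second_width Half-widths in nm (positive).
#' @return [eem] with scatter cells masked; the count of newly masked cells is
#'   attached as attribute \code{"n_excised"}.
#' @export
excise_scatter <- function(x, first_width = 15, second_width = 15) {
  if (first_width <= 0 || second_width <= 0) stop("widths must be positive")
  d1 <- abs(outer(x$excitation, x$emission, function(ex, em) em - ex))
  d2 <- abs(outer(x$excitation, x$emission, function(ex, em) em - 2 * ex))
  hit <- d1 <= first_width | d2 <= second_width
  newly <- sum(hit & !x$mask)
  out <- eem(x$excitation, x$emission, x$intensity,
             mask = x$mask | hit, units_tag = x$units_tag)
  attr(out, "n_excised") <- newly
  out
}

#' Convert an EEM to quinine sulfate units
#'
#' A single multiplicative calibration factor (default 1 = arbitrary units);
#' the instrument calibration itself is accepted as an input scale factor.
#'
#' @param x An [eem].
#' @param factor QSU per arbitrary unit.
#' @export
to_qsu <- function(x, factor = 1) {
  eem(x$excitation, x$emission, x$intensity * factor,
      mask = x$mask, units_tag = "qsu")
}

# Emission-scan intensity at (ex within ex_tol of target, em exact via linear
# interpolation along the emission axis). Returns NA when the needed cells are
# masked.
.em_interp <- function(x, ex_target, em_targets, ex_tol = 2.5) {
  i <- which.min(abs(x$excitation - ex_target))
  if (abs(x$excitation[i] - ex_target) > ex_tol) {
    return(rep(NA_real_, length(em_targets)))
  }
  row <- x$intensity[i, ]
  ok <- !x$mask[i, ]
  if (sum(ok) < 2) return(rep(NA_real_, length(em_targets)))
  em <- x$emission[ok]
  if (any(em_targets < min(em) | em_targets > max(em))) {
    return(rep(NA_real_, length(em_targets)))
  }
  stats::approx(em, row[ok], xout = em_targets)$y
}

#' Fluorescence index (FI)
#'
#' Ratio of emission intensity at 470 nm to that at 520 nm at excitation
#' 370 nm (nearest excitation row within 2.5 nm; emission linearly
#' interpolated onto 470/520 exactly). Returns \code{NA} with a message when
#' the denominator is non-positive or the needed cells are masked.
#'
#' @param x An [eem].
#' @export
fluorescence_index <- function(x) {
  v <- .em_interp(x, 370, c(470, 520))
  if (anyNA(v) || v[2] <= 0) return(NA_real_)
  v[1] / v[2]
}

#' Freshness index (beta/alpha)
#'
#' Emission intensity at 380 nm divided by the maximum emission intensity
#' between 420 and 435 nm, at excitation 310 nm.
#'
#' @param x An [eem].
#' @export
freshness_index <- function(x) {
  num <- .em_interp(x, 310, 380)
  i <- which.min(abs(x$excitation - 310))
  if (abs(x$excitation[i] - 310) > 2.5) return(NA_real_)
  win <- x$emission >= 420 & x$emission <= 435 & !x$mask[i, ]
  if (!any(win) || is.na(num)) return(NA_real_)
  mx <- max(x$intensity[i, win])
  if (mx <= 0) return(NA_real_)
  num / mx
}

#' Humification index (HIX), both common formulations
#'
#' On a low-excitation row, let H be the trapezoidal area under the emission
#' spectrum over 435-480 nm and L the area over 300-345 nm. The bounded
#' formulation is \code{hix_ohno = H / (H + L)} (in \verb{[0, 1]}); the
#' unbounded one is \code{hix_zsolnay = H / L} (missing when L = 0). The
#' classical definition uses excitation 254 nm; on grids that start above
#' 254 nm the lowest available excitation row is used and reported in the
#' result.
#'
#' @param x An [eem].
#' @param excitation Target excitation (nm); defaults to 254, falling back to
#'   the lowest available row when the grid starts higher.
#' @return A list with \code{hix_ohno}, \code{hix_zsolnay}, and
#'   \code{excitation_used}.
#' @export
hix <- function(x, excitation = 254) {
  ex_used <- if (min(x$excitation) > excitation) min(x$excitation) else {
    x$excitation[which.min(abs(x$excitation - excitation))]
  }
  i <- which.min(abs(x$excitation - ex_used))
  area <- function(lo, hi) {
    ok <- !x$mask[i, ]
    em <- x$emission[ok]
    if (sum(ok) < 2 || min(em) > lo || max(em) < hi) return(NA_real_)
    grid <- sort(unique(c(lo, hi, x$emission[x$emission >= lo & x$emission <= hi])))
    y <- stats::approx(em, x$intensity[i, ok], xout = grid)$y
    pracma::trapz(grid, y)
  }
  h <- area(435, 480)
  l <- area(300, 345)
  if (is.na(h) || is.na(l)) {
    return(list(hix_ohno = NA_real_, hix_zsolnay = NA_real_,
                excitation_used = ex_used))
  }
  list(
    hix_ohno = if (h + l > 0) h / (h + l) else 0,
    hix_zsolnay = if (l > 0) h / l else if (h > 0) NA_real_ else 0,
    excitation_used = ex_used
  )
}

#' All scalar fluorescence indices for one EEM
#'
#' @param x An [eem] (already blank-subtracted / corrected / excised as
#'   desired).
#' @return One-row data frame with \code{fi}, \code{freshness},
#'   \code{hix_ohno}, \code{hix_zsolnay}, \code{hix_excitation}.
#' @export
fluorescence_indices <- function(x) {
  hh <- hix(x)
  data.frame(fi = fluorescence_index(x),
             freshness = freshness_index(x),
             hix_ohno = hh$hix_ohno,
             hix_zsolnay = hh$hix_zsolnay,
             hix_excitation = hh$excitation_used)
}

#' Read / write the EEM CSV dialect
#'
#' First row = emission grid, first column = excitation grid, body =
#' intensities, empty cell = masked. Reader and writer round-trip exactly.
#'
#' @param path File path.
#' @param units_tag Units tag attached on read.
#' @export
read_eem_csv <- function(path, units_tag = "raw") {
  d <- utils::read.csv(path, header = FALSE, comment.char = "#")
  em <- as.numeric(d[1, -1])
  ex <- as.numeric(d[-1, 1])
  body <- as.matrix(d[-1, -1])
  mode(body) <- "numeric"
  dimnames(body) <- NULL
  eem(ex, em, body, units_tag = units_tag)
}

#' @param x An [eem] to write.
#' @rdname read_eem_csv
#' @export
write_eem_csv <- function(x, path) {
  body <- x$intensity
  body[x$mask] <- NA
  d <- rbind(c(NA, x$emission), cbind(x$excitation, body))
  utils::write.table(d, path, sep = ",", na = "", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
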