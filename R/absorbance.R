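# CDOM absorbance metrics: Napierian coefficients, SUVA254,
# spectral slopes over fixed windows, and the slope ratio.

#' Create an absorbance spectrum
#'
#' @param wavelengths Strictly increasing wavelength grid (nm).
#' @param absorbance Decadic absorbance (dimensionless), same length.
#' @param path_length Cuvette path length in metres (default 0.01 m = 1 cm).
#' @return An object of class \code{absorbance_spectrum}.
#' @export
absorbance_spectrum <- function(wavelengths, absorbance, path_length = 0.01) {
  if (length(wavelengths) != length(absorbance)) {
    stop("wavelengths and absorbance must have the same length")
  }
  if (any(diff(wavelengths) <= 0)) stop("wavelengths must be strictly increasing")
  if (path_length <= 0) stop("path_length must be positive")
  structure(list(wavelengths = as.numeric(wavelengths),
                 absorbance = as.numeric(absorbance),
                 path_length = path_length),
            class = "absorbance_spectrum")
}

#' @export
print.absorbance_spectrum <- function(x, ...) {
  cat(sprintf("absorbance spectrum: %d points, %.0f-%.0f nm, path %.3g m\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              x$path_length))
  invisible(x)
}

.abs_at <- function(spec, wavelength) {
  rng <- range(spec$wavelengths)
  if (any(wavelength < rng[1] | wavelength > rng[2])) {
    stop(sprintf("wavelength outside spectrum range %g-%g nm", rng[1], rng[2]))
  }
  stats::approx(spec$wavelengths, spec$absorbance, xout = wavelength)$y
}

#' Decadic absorption coefficient (m^-1)
#'
#' A(lambda) / path_length with linear interpolation on the grid.
#'
#' @param spec An [absorbance_spectrum].
#' @param wavelength Wavelength(s) in nm, within the spectrum range.
#' @export
decadic_coefficient <- function(spec, wavelength) {
  .abs_at(spec, wavelength) / spec$path_length
}

#' Napierian absorption coefficient (m^-1)
#'
#' a(lambda) = ln(10) * A(lambda) / path_length, the convention for CDOM
#' absorption coefficients; A(lambda) is linearly interpolated on the grid.
#'
#' @inheritParams decadic_coefficient
#' @export
napierian_coefficient <- function(spec, wavelength) {
  log(10) * decadic_coefficient(spec, wavelength)
}

#' SUVA254: DOC-specific UV absorbance at 254 nm
#'
#' Decadic absorption coefficient at 254 nm (m^-1) divided by the DOC
#' concentration (mg-C L^-1) — the Weishaar convention. The companion
#' Napierian-based value is \code{napierian_coefficient(spec, 254) / doc}
#' and is also emitted by [absorbance_indices()].
#'
#' @param spec An [absorbance_spectrum] covering 254 nm.
#' @param doc DOC concentration, mg-C per litre; must be positive.
#' @return SUVA254 in L mg-C^-1 m^-1.
#' @export
suva254 <- function(spec, doc) {
  if (doc <= 0) stop("doc must be positive")
  decadic_coefficient(spec, 254) / doc
}

#' Spectral slope of the absorbance exponential decay
#'
#' Ordinary least squares of ln a(lambda) on lambda over the grid points in
#' \verb{[lo, hi]}; returns S = -(fitted slope) so that a steeper decay gives a
#' larger positive S (nm^-1). The regression is on the log-transformed
#' coefficients, not a nonlinear exponential fit.
#'
#' @param spec An [absorbance_spectrum].
#' @param lo,hi Window bounds in nm (inclusive), \code{lo < hi}.
#' @return Spectral slope in nm^-1.
#' @export
spectral_slope <- function(spec, lo, hi) {
  if (lo >= hi) stop("lo must be < hi")
  sel <- spec$wavelengths >= lo & spec$wavelengths <= hi
  if (sum(sel) < 3) stop("fewer than 3 grid points in window")
  lam <- spec$wavelengths[sel]
  a <- log(10) * spec$absorbance[sel] / spec$path_length
  bad <- a <= 0
  if (any(bad)) {
    stop("non-positive absorbance at wavelengths: ",
         paste(lam[bad], collapse = ", "))
  }
  fit <- stats::lm.fit(cbind(1, lam), log(a))
  -unname(fit$coefficients[2])
}

#' Slope ratio S275-295 / S350-400
#'
#' Returns \code{NA} (a propagating missing value, not an error) when the
#' denominator slope is zero so batch runs continue.
#'
#' @param s275 Spectral slope over 275-295 nm (nm^-1).
#' @param s350 Spectral slope over 350-400 nm (nm^-1).
#' @export
slope_ratio <- function(s275, s350) {
  ifelse(s350 == 0, NA_real_, s275 / s350)
}

#' All absorbance indices for one sample
#'
#' Computes the full index set: Napierian and decadic a254 (m^-1), SUVA254
#' (decadic-based, Weishaar convention; the Napierian variant is included as
#' \code{suva254_napierian}), spectral slopes S275-295 and S350-400, and the
#' slope ratio.
#'
#' @param spec An [absorbance_spectrum] covering at least 250-400 nm.
#' @param doc DOC concentration (mg-C L^-1).
#' @return One-row data frame.
#' @export
absorbance_indices <- function(spec, doc) {
  s275 <- spectral_slope(spec, 275, 295)
  s350 <- spectral_slope(spec, 350, 400)
  data.frame(
    a254 = napierian_coefficient(spec, 254),
    a254_decadic = decadic_coefficient(spec, 254),
    suva254 = suva254(spec, doc),
    suva254_napierian = napierian_coefficient(spec, 254) / doc,
    s275_295 = s275,
    s350_400 = s350,
    s_r = slope_ratio(s275, s350)
  )
}

#' Read / write an absorbance spectrum CSV
#'
#' Dialect: columns \code{wavelength_nm, absorbance}, one file per sample.
#'
#' @param path File path.
#' @param path_length Path length in metres attached to the returned spectrum.
#' @return [read_absorbance_csv()] returns an [absorbance_spectrum].
#' @export
read_absorbance_csv <- function(path, path_length = 0.01) {
  d <- utils::read.csv(path, comment.char = "#")
  absorbance_spectrum(d$wavelength_nm, d$absorbance, path_length)
}

#' @param spec An [absorbance_spectrum] to write.
#' @rdname read_absorbance_csv
#' @export
write_absorbance_csv <- function(spec, path) {
  utils::write.csv(data.frame(wavelength_nm = spec$wavelengths,
                              absorbance = spec$absorbance),
                   path, row.names = FALSE)
  invisible(path)
}
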