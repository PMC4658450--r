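# Elemental-formula arithmetic for CHNOSP molecular formulae:
# monoisotopic mass, elemental ratios, DBE, modified aromaticity index,
# and stoichiometric compound-class assignment.

#' Monoisotopic atomic masses used throughout the package
#'
#' IUPAC monoisotopic masses of the most abundant isotopes \code{12C},
#' \code{1H}, \code{14N}, \code{16O}, \code{32S}, \code{31P}, plus the
#' proton mass used to convert a neutral mass to its deprotonated
#' \verb{[M-H]-} ion mass.
#'
#' @format Named numeric vector (Da).
#' @export
ELEMENT_MASSES <- c(
  c = 12.0,
  h = 1.00782503207,
  n = 14.0030740048,
  o = 15.9949146196,
  s = 31.97207100,
  p = 30.97376163
)

#' Proton mass (Da): monoisotopic 1H minus the electron mass
#' @rdname ELEMENT_MASSES
#' @export
PROTON_MASS <- 1.00727645

#' Compound-class labels
#'
#' The fixed set of stoichiometric compound classes a molecular formula can be
#' assigned to. \code{OTHER} collects formulae matched by no named rule; it is
#' always reported separately and never merged into a named class.
#'
#' @export
COMPOUND_CLASSES <- c(
  "black_carbon", "polyphenol", "highly_unsaturated",
  "unsaturated_aliphatic", "saturated_fatty_acid", "sugar",
  "peptide", "other"
)

.check_formula <- function(f) {
  need <- c("c", "h", "n", "o", "s", "p")
  if (!all(need %in% names(f))) {
    stop("formula must carry element counts c, h, n, o, s, p")
  }
  if (any(f$c < 1)) stop("carbon count must be >= 1")
  if (any(unlist(f[need]) < 0)) stop("element counts must be non-negative")
  invisible(f)
}

#' Create a molecular formula
#'
#' A molecular formula is a plain list of non-negative integer element counts
#' with value semantics: two formulae with equal counts compare equal.
#'
#' @param c,h,n,o,s,p Element counts (non-negative integers; \code{c >= 1}).
#' @return An object of class \code{molecular_formula}.
#' @examples
#' molecular_formula(c = 16, h = 32, o = 2)
#' @export
molecular_formula <- function(c, h = 0, n = 0, o = 0, s = 0, p = 0) {
  f <- list(c = as.integer(c), h = as.integer(h), n = as.integer(n),
            o = as.integer(o), s = as.integer(s), p = as.integer(p))
  .check_formula(f)
  structure(f, class = "molecular_formula")
}

#' @export
print.molecular_formula <- function(x, ...) {
  cat(format_formula(x), "\n")
  invisible(x)
}

#' @export
`==.molecular_formula` <- function(e1, e2) {
  all(unlist(e1[c("c", "h", "n", "o", "s", "p")]) ==
      unlist(e2[c("c", "h", "n", "o", "s", "p")]))
}

#' Format a molecular formula as a Hill-like string
#'
#' Writes \code{"C10H12N2O3S1"}; elements with zero count are omitted.
#' \code{parse_formula} is its inverse.
#'
#' @param f A \code{molecular_formula} or a data frame with columns
#'   \code{c,h,n,o,s,p} (vectorised).
#' @return Character vector of formula strings.
#' @export
format_formula <- function(f) {
  cnt <- if (is.data.frame(f)) f else as.data.frame(unclass(f))
  sym <- c(c = "C", h = "H", n = "N", o = "O", s = "S", p = "P")
  out <- rep("", nrow(cnt))
  for (el in names(sym)) {
    v <- cnt[[el]]
    out <- paste0(out, ifelse(v > 0, paste0(sym[[el]], v), ""))
  }
  out
}

#' Parse a Hill-like formula string
#'
#' Accepts strings like \code{"C16H32O2"} or \code{"C10H12N2O3S1P0"}; element
#' letters may appear in any order, zero counts may be omitted, and a bare
#' element letter means count 1.
#'
#' @param x Character vector of formula strings.
#' @return A data frame with integer columns \code{c,h,n,o,s,p}, one row per
#'   input string.
#' @export
parse_formula <- function(x) {
  out <- data.frame(c = integer(length(x)), h = integer(length(x)),
                    n = integer(length(x)), o = integer(length(x)),
                    s = integer(length(x)), p = integer(length(x)))
  for (i in seq_along(x)) {
    m <- gregexpr("([CHNOSP])([0-9]*)", x[[i]])[[1]]
    if (m[1] == -1) stop("cannot parse formula string: ", x[[i]])
    parts <- regmatches(x[[i]], gregexpr("([CHNOSP])([0-9]*)", x[[i]]))[[1]]
    for (pt in parts) {
      el <- tolower(substr(pt, 1, 1))
      num <- substr(pt, 2, nchar(pt))
      out[[el]][i] <- if (nzchar(num)) as.integer(num) else 1L
    }
  }
  out
}

.counts_df <- function(f) {
  if (inherits(f, "molecular_formula")) {
    as.data.frame(unclass(f))
  } else if (is.data.frame(f)) {
    f
  } else if (is.character(f)) {
    parse_formula(f)
  } else {
    stop("expected a molecular_formula, counts data frame, or formula string")
  }
}

#' Neutral monoisotopic mass of a molecular formula
#'
#' Sum over elements of count times the IUPAC monoisotopic atomic mass
#' (12C, 1H, 14N, 16O, 32S, 31P).
#'
#' @inheritParams format_formula
#' @return Numeric vector of neutral monoisotopic masses (Da).
#' @examples
#' monoisotopic_mass(molecular_formula(16, 32, o = 2))  # palmitic acid
#' @export
monoisotopic_mass <- function(f) {
  cnt <- .counts_df(f)
  with(cnt, c * ELEMENT_MASSES[["c"]] + h * ELEMENT_MASSES[["h"]] +
         n * ELEMENT_MASSES[["n"]] + o * ELEMENT_MASSES[["o"]] +
         s * ELEMENT_MASSES[["s"]] + p * ELEMENT_MASSES[["p"]])
}

#' Mass of the deprotonated ion of a formula
#'
#' \verb{[M-H]-} ion mass: neutral monoisotopic mass minus the proton mass.
#'
#' @inheritParams format_formula
#' @return Numeric vector (Da).
#' @export
ion_mass <- function(f) monoisotopic_mass(f) - PROTON_MASS

#' Modified aromaticity index (AI-mod)
#'
#' AI-mod = (1 + C - 0.5 O - S - 0.5 H) / (C - 0.5 O - N - S - P), with half
#' of the oxygen discounted to account for carboxyl groups. A negative
#' numerator or non-positive denominator is clamped to 0 (fully saturated or
#' degenerate formulae carry no aromaticity).
#'
#' @inheritParams format_formula
#' @return Numeric vector of AI-mod values (>= 0).
#' @examples
#' ai_mod(molecular_formula(15, 12, o = 7))  # a flavonoid-like polyphenol
#' @export
ai_mod <- function(f) {
  cnt <- .counts_df(f)
  num <- 1 + cnt$c - 0.5 * cnt$o - cnt$s - 0.5 * cnt$h
  den <- cnt$c - 0.5 * cnt$o - cnt$n - cnt$s - cnt$p
  out <- ifelse(num < 0 | den <= 0, 0, num / den)
  pmax(out, 0)
}

#' Double-bond equivalents
#'
#' DBE = 1 + C - H/2 + N/2 + P/2 (rings plus double bonds of the neutral
#' molecule; O and S contribute zero).
#'
#' @inheritParams format_formula
#' @return Numeric vector.
#' @export
dbe <- function(f) {
  cnt <- .counts_df(f)
  1 + cnt$c - cnt$h / 2 + cnt$n / 2 + cnt$p / 2
}

#' Stoichiometric compound-class assignment
#'
#' Assigns each formula to exactly one class by evaluating, in fixed
#' precedence order on (AI-mod, H/C, O/C, N):
#' \enumerate{
#'   \item sugar: O/C >= 0.9
#'   \item black carbon (condensed aromatic): AI-mod >= 0.67
#'   \item polyphenol (aromatic): 0.5 <= AI-mod < 0.67
#'   \item saturated fatty acid: H/C >= 2 and O/C < 0.9
#'   \item peptide: 1.5 <= H/C < 2, O/C < 0.9, N > 0
#'   \item unsaturated aliphatic: 1.5 <= H/C < 2, O/C < 0.9, N = 0
#'   \item highly unsaturated: AI-mod < 0.5, H/C < 1.5, O/C < 0.9
#'   \item other: anything left (reported separately, never merged)
#' }
#' The precedence makes overlapping conditions (e.g. AI-mod < 0.5 with
#' O/C >= 0.9) resolve deterministically.
#'
#' @inheritParams format_formula
#' @return Character vector of class labels from [COMPOUND_CLASSES].
#' @export
classify_formula <- function(f) {
  cnt <- .counts_df(f)
  ai <- ai_mod(cnt)
  hc <- cnt$h / cnt$c
  oc <- cnt$o / cnt$c
  out <- rep("other", nrow(cnt))
  undecided <- rep(TRUE, nrow(cnt))
  take <- function(cond, label) {
    hit <- undecided & cond
    out[hit] <<- label
    undecided[hit] <<- FALSE
  }
  take(oc >= 0.9, "sugar")
  take(ai >= 0.67, "black_carbon")
  take(ai >= 0.5 & ai < 0.67, "polyphenol")
  take(hc >= 2 & oc < 0.9, "saturated_fatty_acid")
  take(hc >= 1.5 & hc < 2 & oc < 0.9 & cnt$n > 0, "peptide")
  take(hc >= 1.5 & hc < 2 & oc < 0.9 & cnt$n == 0, "unsaturated_aliphatic")
  take(ai < 0.5 & hc < 1.5 & oc < 0.9, "highly_unsaturated")
  out
}

#' Annotate a table of molecular formulae
#'
#' Adds the derived chemistry every downstream stage consumes: formula string,
#' neutral and \verb{[M-H]-} masses, O/C and H/C ratios, DBE, AI-mod, compound
#' class, and elemental-group membership flags (CHO-only, contains N / S / P).
#'
#' @param f Data frame with integer columns \code{c,h,n,o,s,p} (or a character
#'   vector of formula strings).
#' @return The input counts plus annotation columns.
#' @export
annotate_formulae <- function(f) {
  cnt <- .counts_df(f)
  cnt$formula <- format_formula(cnt)
  cnt$neutral_mass <- monoisotopic_mass(cnt)
  cnt$ion_mz <- cnt$neutral_mass - PROTON_MASS
  cnt$oc_ratio <- cnt$o / cnt$c
  cnt$hc_ratio <- cnt$h / cnt$c
  cnt$dbe <- dbe(cnt)
  cnt$ai_mod <- ai_mod(cnt)
  cnt$compound_class <- classify_formula(cnt)
  cnt$cho_only <- cnt$n == 0 & cnt$s == 0 & cnt$p == 0
  cnt$has_n <- cnt$n > 0
  cnt$has_s <- cnt$s > 0
  cnt$has_p <- cnt$p > 0
  cnt
}
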