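#' Monoisotopic mass constants
#'
#' IUPAC monoisotopic atomic masses (Da) for the elements supported by the
#' formula parser, together with the proton and electron masses used for
#' adduct arithmetic. Positive-mode TOF data reproduce printed reference m/z
#' values only when the *proton* mass (not the hydrogen atom mass) is added
#' for \[M+H\]+ and the electron mass subtracted for intrinsic cations \[M\]+.
#'
#' @return Named list with elements `atomic` (named numeric vector of
#'   monoisotopic atomic masses), `proton` and `electron` (Da).
#' @examples
#' mass_constants()$atomic[["C"]]  # 12 exactly
#' @export
mass_constants <- function() {
  list(
    atomic = c(
      C  = 12.0,
      H  = 1.0078250319,
      N  = 14.0030740052,
      O  = 15.9949146221,
      S  = 31.97207069,
      Na = 22.98976928,
      P  = 30.97376200,
      K  = 38.96370649,
      Cl = 34.96885268
    ),
    proton   = 1.00727646688,
    electron = 0.00054857990
  )
}

#' Parse an elemental formula in Hill notation
#'
#' Parses strings such as `"C6H14N2O2"` into named integer element counts.
#' Element symbols are case-sensitive; counts default to 1. Unknown element
#' symbols and empty formulas are rejected.
#'
#' @param formula Single formula string, e.g. `"C10H17N3O6S"`.
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("C6H14N2O2")
#' @export
parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || is.na(formula) ||
      !nzchar(formula)) {
    stop("formula must be a single non-empty string", call. = FALSE)
  }
  toks <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1L]]
  if (!identical(paste(toks, collapse = ""), formula)) {
    stop("malformed formula string: '", formula, "'", call. = FALSE)
  }
  el <- sub("[0-9]*$", "", toks)
  n  <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", toks)))
  n[is.na(n)] <- 1L
  known <- names(mass_constants()$atomic)
  bad <- setdiff(el, known)
  if (length(bad)) {
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  counts <- tapply(n, factor(el, levels = unique(el)), sum)
  counts <- stats::setNames(as.integer(counts), names(counts))
  if (sum(counts) < 1L) stop("formula has no atoms", call. = FALSE)
  counts
}

#' Monoisotopic mass of a molecule
#'
#' Sum of element counts times monoisotopic atomic masses.
#'
#' @param formula Formula string in Hill notation, or a named integer vector
#'   as returned by [parse_formula()].
#' @return Monoisotopic mass in Da (full float precision).
#' @examples
#' monoisotopic_mass("C6H14N2O2")  # lysine, 146.1055 Da
#' @export
monoisotopic_mass <- function(formula) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  if (is.null(names(counts)) || any(counts < 0)) {
    stop("formula counts must be a named non-negative vector", call. = FALSE)
  }
  am <- mass_constants()$atomic
  bad <- setdiff(names(counts), names(am))
  if (length(bad)) {
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (sum(counts) < 1L) stop("formula has no atoms", call. = FALSE)
  sum(am[names(counts)] * counts)
}

#' m/z of a singly charged adduct
#'
#' Positive-mode adducts supported by the pipeline: `"M+H"` (protonated
#' molecule, mass + proton mass) and `"M"` (intrinsic cation such as a
#' quaternary ammonium, mass - electron mass). Rounding is left to the
#' caller; [round_mz()] applies the 4-decimal report convention.
#'
#' @param mass Neutral monoisotopic mass (Da) for `"M+H"`, or the cation
#'   formula mass for `"M"`. Must be positive.
#' @param adduct `"M+H"` or `"M"`.
#' @return m/z in Da.
#' @examples
#' adduct_mz(monoisotopic_mass("C6H14N2O2"), "M+H")  # lysine 147.1128
#' @export
adduct_mz <- function(mass, adduct = c("M+H", "M")) {
  adduct <- match.arg(adduct)
  if (!is.numeric(mass) || any(!is.finite(mass)) || any(mass <= 0)) {
    stop("mass must be positive and finite", call. = FALSE)
  }
  k <- mass_constants()
  switch(adduct,
    "M+H" = mass + k$proton,
    "M"   = mass - k$electron
  )
}

#' Relative mass deviation in parts per million
#'
#' `(measured - theoretical) / theoretical * 1e6`, sign preserved. This is
#' the accurate-mass matching criterion (3 ppm acceptance by default).
#'
#' @param measured,theoretical m/z values in Da; `theoretical` must be > 0.
#' @return Signed ppm deviation.
#' @examples
#' ppm_deviation(100.0001, 100)  # +1 ppm
#' @export
ppm_deviation <- function(measured, theoretical) {
  if (any(!is.finite(theoretical)) || any(theoretical <= 0)) {
    stop("theoretical m/z must be positive", call. = FALSE)
  }
  (measured - theoretical) / theoretical * 1e6
}

#' Absolute mass deviation in milli-Dalton
#'
#' `(theoretical - measured) * 1000`, the reference-minus-measured convention
#' used in printed deviation columns (reported at 1 decimal place).
#'
#' @param measured,theoretical m/z values in Da; both must be > 0.
#' @return Deviation in mDa.
#' @examples
#' mda_deviation(132.0740, 132.0768)  # 2.8 mDa
#' @export
mda_deviation <- function(measured, theoretical) {
  if (any(!is.finite(measured)) || any(measured <= 0) ||
      any(!is.finite(theoretical)) || any(theoretical <= 0)) {
    stop("m/z values must be positive", call. = FALSE)
  }
  (theoretical - measured) * 1000
}

#' Round an m/z value to the 4-decimal report convention
#'
#' Uses R's IEEE round-half-even, matching how reference tables print
#' theoretical and measured m/z.
#'
#' @param mz Numeric m/z value(s).
#' @param digits Decimal places (default 4).
#' @return Rounded value(s).
#' @export
round_mz <- function(mz, digits = 4L) round(mz, digits)

#' Theoretical m/z from formula and adduct
#'
#' Convenience composition of [monoisotopic_mass()] and [adduct_mz()].
#'
#' @param formula Formula string (for `"M"` adducts, the cation formula).
#' @param adduct `"M+H"` or `"M"`.
#' @return Theoretical m/z (unrounded).
#' @examples
#' theoretical_mz("C5H14NO", "M")  # choline cation 104.1070
#' @export
theoretical_mz <- function(formula, adduct = "M+H") {
  adduct_mz(monoisotopic_mass(formula), adduct)
}
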