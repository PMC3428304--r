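#' Define a stable-isotope labeling scheme
#'
#' Cultivating a producer strain on medium in which one element is supplied
#' as a heavy stable isotope (e.g. all nitrogen as 15N, all sulfate as 34S)
#' shifts each metabolite's mass by (number of atoms of that element) x
#' (per-atom mass difference). The observed shift therefore counts the atoms.
#'
#' @param isotope Heavy isotope name: `"15N"`, `"34S"`, `"13C"` or `"2H"`.
#' @param enrichment Fraction of atoms actually replaced, in \[0, 1\].
#'   Defaults to 1: the monoisotopic peak of a labeled compound corresponds
#'   to complete substitution even when the medium is only 90-98 atom%
#'   enriched, so full labeling is the interpretation applied to observed
#'   shifts.
#' @return An object of class `isotope_label` with fields `element`,
#'   `heavy_isotope`, `per_atom_delta` (Da) and `enrichment`.
#' @examples
#' isotope_label("34S")  # per-atom shift 1.9958 Da
#' @export
isotope_label <- function(isotope, enrichment = 1) {
  if (!isotope %in% names(.ISOTOPE_MASS)) {
    stop("unknown isotope '", isotope, "'; supported: ",
         paste(names(.ISOTOPE_MASS), collapse = ", "))
  }
  if (!is.numeric(enrichment) || length(enrichment) != 1 ||
      enrichment < 0 || enrichment > 1) {
    stop("'enrichment' must be a single number in [0, 1]")
  }
  el <- .ISOTOPE_ELEMENT[[isotope]]
  structure(list(element = el, heavy_isotope = isotope,
                 per_atom_delta = .ISOTOPE_MASS[[isotope]] - .ELEMENT_MASS[[el]],
                 enrichment = enrichment),
            class = "isotope_label")
}

#' @export
print.isotope_label <- function(x, ...) {
  cat("<isotope_label> ", x$heavy_isotope, " for ", x$element,
      ": +", sprintf("%.6f", x$per_atom_delta), " Da/atom, enrichment ",
      x$enrichment, "\n", sep = "")
  invisible(x)
}

#' Mass shift of a formula under full isotope labeling
#'
#' @param f A [chem_formula].
#' @param label An [isotope_label].
#' @return Shift in Da: atom count x per-atom delta x enrichment. Zero when
#'   the formula contains no atoms of the labeled element.
#' @examples
#' isotope_shift(peptide_formula("GTHLYTITP"), isotope_label("15N"))
#' @export
isotope_shift <- function(f, label) {
  stopifnot(inherits(label, "isotope_label"))
  f <- chem_formula(f)
  f$counts[[label$element]] * label$per_atom_delta * label$enrichment
}

#' Nominal (integer) label shift
#'
#' Integer counterpart of [isotope_shift()]: atom count times the integer
#' isotope mass difference (15N - 14N = 1, 34S - 32S = 2). This is the shift
#' a low-resolution instrument prints, e.g. +4 Da for two 34S-labeled
#' sulfur atoms.
#'
#' @inheritParams isotope_shift
#' @return Integer shift in Da.
#' @export
nominal_isotope_shift <- function(f, label) {
  stopifnot(inherits(label, "isotope_label"))
  f <- chem_formula(f)
  per_atom <- round(.ISOTOPE_MASS[[label$heavy_isotope]]) -
    .ELEMENT_NOMINAL[[label$element]]
  as.integer(f$counts[[label$element]] * per_atom)
}

#' Infer the number of labeled atoms from an observed mass shift
#'
#' Inverts the labeling arithmetic: the observed shift divided by the
#' per-atom delta (times enrichment), rounded to the nearest integer, counts
#' the atoms of the labeled element; the residual flags inconsistency.
#'
#' @param observed_shift Observed labeled-minus-unlabeled mass difference, Da.
#' @param label An [isotope_label].
#' @param tol Consistency tolerance as a fraction of the effective per-atom
#'   delta (default 0.3: a residual beyond 30% of one atom's shift marks the
#'   count unreliable).
#' @return A list: `n_atoms` (integer), `residual` (Da, signed), `consistent`
#'   (logical).
#' @examples
#' infer_atom_count(3.99, isotope_label("34S"))  # 2 sulfur atoms
#' @export
infer_atom_count <- function(observed_shift, label, tol = 0.3) {
  stopifnot(inherits(label, "isotope_label"))
  if (!is.numeric(observed_shift) || length(observed_shift) != 1 ||
      !is.finite(observed_shift)) {
    stop("'observed_shift' must be a single finite number")
  }
  if (observed_shift < 0) stop("'observed_shift' must be non-negative")
  per <- label$per_atom_delta * label$enrichment
  n <- as.integer(round(observed_shift / per))
  residual <- observed_shift - n * per
  list(n_atoms = n, residual = residual, consistent = abs(residual) <= tol * per)
}
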