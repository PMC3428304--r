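# Monoisotopic atomic masses (CODATA/IUPAC), >= 6 decimals. Supported element
# set is deliberately small: peptides plus the modifications handled here only
# ever contain C, H, N, O, S.
.ELEMENT_MASS <- c(
  C = 12.000000,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.9720706912
)

# Integer (nominal) atomic masses, used for the integer m/z values that
# low-resolution instruments report.
.ELEMENT_NOMINAL <- c(C = 12L, H = 1L, N = 14L, O = 16L, S = 32L)

# Heavy-isotope masses and their shift relative to the light principal isotope.
.ISOTOPE_MASS <- c(`15N` = 15.0001088984, `34S` = 33.9678669,
                   `13C` = 13.0033548378, `2H` = 2.0141017780)
.ISOTOPE_ELEMENT <- c(`15N` = "N", `34S` = "S", `13C` = "C", `2H` = "H")

.PROTON_MASS <- 1.0072764669

#' Monoisotopic mass of the proton
#'
#' @return Mass in Da of H+ (not the hydrogen atom).
#' @export
proton_mass <- function() .PROTON_MASS

#' Construct an elemental formula
#'
#' An elemental formula is the unit of all mass arithmetic in the package:
#' a non-negative count per element over \{C, H, N, O, S\}, optionally with a
#' number of atoms substituted by a named heavy isotope (e.g. 13 of the
#' nitrogens as 15N). Formulas support `+`, `-` and integer `*`.
#'
#' @param x Either a formula string in Hill-like notation (`"C5H8"`, `"H2O"`,
#'   `"C2H3NO"`) or a named numeric vector of element counts.
#' @param isotope_subs Named integer vector: heavy-isotope name (`"15N"`,
#'   `"34S"`, `"13C"`, `"2H"`) to number of atoms of the corresponding element
#'   carrying that isotope. Must not exceed the element count.
#' @return An object of class `chem_formula`.
#' @examples
#' chem_formula("C5H8")                     # prenyl group
#' chem_formula(c(C = 10, H = 16))          # geranyl group
#' chem_formula("H2O", isotope_subs = NULL)
#' @export
chem_formula <- function(x = character(), isotope_subs = NULL) {
  counts <- if (is.character(x)) {
    if (length(x) > 1) stop("supply a single formula string")
    .parse_formula(if (length(x) == 0) "" else x)
  } else if (is.numeric(x)) {
    if (length(x) > 0 && is.null(names(x))) stop("element counts must be named")
    x
  } else if (inherits(x, "chem_formula")) {
    return(x)
  } else {
    stop("cannot interpret 'x' as an elemental formula")
  }
  full <- stats::setNames(numeric(length(.ELEMENT_MASS)), names(.ELEMENT_MASS))
  unknown <- setdiff(names(counts), names(full))
  if (length(unknown) > 0) {
    stop("unsupported element(s): ", paste(unknown, collapse = ", "),
         " (supported: ", paste(names(full), collapse = ", "), ")")
  }
  full[names(counts)] <- counts
  if (any(full < 0)) stop("element counts must be non-negative")
  if (any(full != round(full))) stop("element counts must be integers")
  subs <- numeric(0)
  if (!is.null(isotope_subs) && length(isotope_subs) > 0) {
    bad <- setdiff(names(isotope_subs), names(.ISOTOPE_MASS))
    if (length(bad) > 0) stop("unknown isotope(s): ", paste(bad, collapse = ", "))
    if (any(isotope_subs < 0)) stop("isotope substitution counts must be non-negative")
    for (iso in names(isotope_subs)) {
      el <- .ISOTOPE_ELEMENT[[iso]]
      if (isotope_subs[[iso]] > full[[el]]) {
        stop("cannot substitute ", isotope_subs[[iso]], " atoms of ", el,
             " as ", iso, ": formula has only ", full[[el]])
      }
    }
    subs <- isotope_subs[isotope_subs > 0]
  }
  structure(list(counts = full, isotope_subs = subs), class = "chem_formula")
}

.parse_formula <- function(s) {
  if (!nzchar(s)) return(numeric(0))
  if (!grepl("^([A-Z][a-z]?[0-9]*)+$", s)) stop("malformed formula string: '", s, "'")
  m <- gregexpr("[A-Z][a-z]?[0-9]*", s)[[1]]
  toks <- regmatches(s, list(m))[[1]]
  els <- sub("[0-9]*$", "", toks)
  ns <- as.numeric(ifelse(grepl("[0-9]", toks), sub("^[A-Za-z]+", "", toks), "1"))
  tapply(ns, els, sum)[unique(els)]
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<chem_formula> ", format(x), "\n", sep = "")
  if (length(x$isotope_subs) > 0) {
    cat("  isotope substitutions: ",
        paste(sprintf("%s x%d", names(x$isotope_subs), x$isotope_subs), collapse = ", "),
        "\n", sep = "")
  }
  cat("  monoisotopic mass: ", sprintf("%.4f", monoisotopic_mass(x)), " Da\n", sep = "")
  invisible(x)
}

#' @export
format.chem_formula <- function(x, ...) {
  cnt <- x$counts[x$counts > 0]
  if (length(cnt) == 0) return("(empty)")
  # Hill order: C, H, then alphabetical
  ord <- c(intersect(c("C", "H"), names(cnt)), sort(setdiff(names(cnt), c("C", "H"))))
  paste0(ord, ifelse(cnt[ord] > 1, cnt[ord], ""), collapse = "")
}

#' @export
`+.chem_formula` <- function(e1, e2) {
  e1 <- chem_formula(e1); e2 <- chem_formula(e2)
  subs <- .merge_subs(e1$isotope_subs, e2$isotope_subs, `+`)
  chem_formula(e1$counts + e2$counts, isotope_subs = subs)
}

#' @export
`-.chem_formula` <- function(e1, e2) {
  if (missing(e2)) stop("unary minus is not defined for formulas")
  e1 <- chem_formula(e1); e2 <- chem_formula(e2)
  res <- e1$counts - e2$counts
  if (any(res < 0)) {
    stop("subtraction would give negative count for: ",
         paste(names(res)[res < 0], collapse = ", "))
  }
  subs <- .merge_subs(e1$isotope_subs, e2$isotope_subs, `-`)
  chem_formula(res, isotope_subs = subs)
}

#' @export
`*.chem_formula` <- function(e1, e2) {
  if (is.numeric(e1)) { k <- e1; f <- e2 } else { k <- e2; f <- e1 }
  if (!is.numeric(k) || length(k) != 1 || k < 0 || k != round(k)) {
    stop("formulas can only be scaled by a single non-negative integer")
  }
  chem_formula(f$counts * k, isotope_subs = if (length(f$isotope_subs)) f$isotope_subs * k)
}

.merge_subs <- function(a, b, op) {
  keys <- union(names(a), names(b))
  if (length(keys) == 0) return(NULL)
  va <- stats::setNames(numeric(length(keys)), keys); va[names(a)] <- a
  vb <- stats::setNames(numeric(length(keys)), keys); vb[names(b)] <- b
  res <- op(va, vb)
  if (any(res < 0)) stop("isotope substitution count would become negative")
  res[res > 0]
}

#' @export
`==.chem_formula` <- function(e1, e2) {
  e1 <- chem_formula(e1); e2 <- chem_formula(e2)
  identical(e1$counts, e2$counts) &&
    identical(sort(names(e1$isotope_subs)), sort(names(e2$isotope_subs))) &&
    all(e1$isotope_subs[names(e1$isotope_subs)] == e2$isotope_subs[names(e1$isotope_subs)])
}

#' Monoisotopic mass of an elemental formula
#'
#' Sums count times monoisotopic atomic mass over the elements; atoms marked
#' as heavy-isotope substitutions contribute the heavy-isotope mass instead.
#'
#' @param f A [chem_formula] (or something coercible to one).
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass(chem_formula("H2O"))   # 18.0106
#' monoisotopic_mass(chem_formula("C5H8"))  # 68.0626, the prenyl increment
#' @export
monoisotopic_mass <- function(f) {
  f <- chem_formula(f)
  m <- sum(f$counts * .ELEMENT_MASS)
  if (length(f$isotope_subs) > 0) {
    deltas <- .ISOTOPE_MASS[names(f$isotope_subs)] -
      .ELEMENT_MASS[.ISOTOPE_ELEMENT[names(f$isotope_subs)]]
    m <- m + sum(f$isotope_subs * deltas)
  }
  m
}

#' Nominal (integer) mass of an elemental formula
#'
#' The classical nominal mass: the sum of integer atomic masses
#' (C = 12, H = 1, N = 14, O = 16, S = 32), with heavy-isotope substitutions
#' contributing their integer mass (15N = 15, 34S = 34). This is the integer
#' a low-resolution instrument reports for a peptide ion; note it is not the
#' rounded monoisotopic mass (a 1.5 kDa peptide ion has a mass excess of
#' about +0.7 Da, so rounding would overshoot by one).
#'
#' @inheritParams monoisotopic_mass
#' @return Integer mass in Da.
#' @export
nominal_mass <- function(f) {
  f <- chem_formula(f)
  m <- sum(f$counts * .ELEMENT_NOMINAL[names(f$counts)])
  if (length(f$isotope_subs) > 0) {
    deltas <- round(.ISOTOPE_MASS[names(f$isotope_subs)]) -
      .ELEMENT_NOMINAL[.ISOTOPE_ELEMENT[names(f$isotope_subs)]]
    m <- m + sum(f$isotope_subs * deltas)
  }
  as.integer(round(m))
}

#' m/z of a protonated ion
#'
#' Positive-mode electrospray adds z protons: m/z = (M + z * m_proton) / z.
#'
#' @inheritParams monoisotopic_mass
#' @param z Charge state, a positive integer (default 1).
#' @return Monoisotopic m/z.
#' @examples
#' protonated_mz(chem_formula("H2O"))  # 19.0178
#' @export
protonated_mz <- function(f, z = 1L) {
  if (!is.numeric(z) || length(z) != 1 || z < 1 || z != round(z)) {
    stop("charge 'z' must be a positive integer")
  }
  (monoisotopic_mass(f) + z * .PROTON_MASS) / z
}

#' Nominal m/z of a protonated ion
#'
#' Integer-mass counterpart of [protonated_mz()]: the proton counts 1 Da.
#'
#' @inheritParams protonated_mz
#' @export
nominal_mz <- function(f, z = 1L) {
  if (!is.numeric(z) || length(z) != 1 || z < 1 || z != round(z)) {
    stop("charge 'z' must be a positive integer")
  }
  (nominal_mass(f) + z) / z
}
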