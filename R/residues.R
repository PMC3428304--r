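# Residue (dehydrated monomer) compositions of the 20 standard amino acids.
# A peptide chain is the element-wise sum of these; a free linear peptide adds
# one H2O for its termini, a head-to-tail macrocycle adds nothing.
.RESIDUE_COMPOSITION <- list(
  G = c(C = 2,  H = 3,  N = 1, O = 1),
  A = c(C = 3,  H = 5,  N = 1, O = 1),
  S = c(C = 3,  H = 5,  N = 1, O = 2),
  P = c(C = 5,  H = 7,  N = 1, O = 1),
  V = c(C = 5,  H = 9,  N = 1, O = 1),
  T = c(C = 4,  H = 7,  N = 1, O = 2),
  C = c(C = 3,  H = 5,  N = 1, O = 1, S = 1),
  L = c(C = 6,  H = 11, N = 1, O = 1),
  I = c(C = 6,  H = 11, N = 1, O = 1),
  N = c(C = 4,  H = 6,  N = 2, O = 2),
  D = c(C = 4,  H = 5,  N = 1, O = 3),
  Q = c(C = 5,  H = 8,  N = 2, O = 2),
  K = c(C = 6,  H = 12, N = 2, O = 1),
  E = c(C = 5,  H = 7,  N = 1, O = 3),
  M = c(C = 5,  H = 9,  N = 1, O = 1, S = 1),
  H = c(C = 6,  H = 7,  N = 3, O = 1),
  F = c(C = 9,  H = 9,  N = 1, O = 1),
  R = c(C = 6,  H = 12, N = 4, O = 1),
  Y = c(C = 9,  H = 9,  N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1)
)

#' Elemental composition of a standard amino-acid residue
#'
#' Returns the dehydrated-monomer (residue) composition, i.e. the amino acid
#' minus one water, as found inside a peptide chain.
#'
#' @param aa A single one-letter code for one of the 20 standard amino acids.
#'   Ambiguity codes (B, Z, X, ...) are rejected.
#' @return A [chem_formula].
#' @examples
#' residue_formula("G")  # C2H3NO
#' @export
residue_formula <- function(aa) {
  if (!is.character(aa) || length(aa) != 1 || nchar(aa) != 1) {
    stop("'aa' must be a single one-letter amino-acid code")
  }
  comp <- .RESIDUE_COMPOSITION[[aa]]
  if (is.null(comp)) {
    stop("'", aa, "' is not a standard amino-acid code; ",
         "only the 20 standard residues have a defined composition")
  }
  chem_formula(comp)
}

#' Elemental composition of a peptide
#'
#' Sums residue compositions over the sequence. A head-to-tail cyclic peptide
#' is the bare sum (the macrocyclizing condensation consumes the terminal
#' water); a linear peptide additionally carries one H2O.
#'
#' @param core Amino-acid sequence (one-letter codes, 20 standard residues).
#' @param topology `"cyclic"` (head-to-tail macrocycle, the default for
#'   cyanobactin products) or `"linear"`.
#' @return A [chem_formula].
#' @examples
#' peptide_formula("GG", "cyclic")               # C4H6N2O2
#' protonated_mz(peptide_formula("GTHLYTITP"))   # 984.5149
#' @export
peptide_formula <- function(core, topology = c("cyclic", "linear")) {
  topology <- match.arg(topology)
  if (!is.character(core) || length(core) != 1 || !nzchar(core)) {
    stop("'core' must be a non-empty amino-acid string")
  }
  res <- strsplit(core, "")[[1]]
  bad <- setdiff(res, names(.RESIDUE_COMPOSITION))
  if (length(bad) > 0) {
    stop("non-standard residue(s) in core '", core, "': ",
         paste(unique(bad), collapse = ", "))
  }
  counts <- Reduce(`+`, lapply(.RESIDUE_COMPOSITION[res], function(x) {
    full <- c(C = 0, H = 0, N = 0, O = 0, S = 0)
    full[names(x)] <- x
    full
  }))
  f <- chem_formula(counts)
  if (topology == "linear") f <- f + chem_formula("H2O")
  f
}

#' Count occurrences of a residue in a sequence
#' @param core Amino-acid string.
#' @param residue Single one-letter code.
#' @return Integer count.
#' @keywords internal
count_residue <- function(core, residue) {
  lengths(regmatches(core, gregexpr(residue, core, fixed = TRUE)))
}
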