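# Post-translational / analytical modifications of cyanobactin products.
# The table ships as a plain-text TSV (inst/extdata/modifications.tsv) so the
# constants are auditable; it is parsed once per session.
.mod_cache <- new.env(parent = emptyenv())

#' Modification table
#'
#' The modifications the variant machinery knows about, each as a signed
#' elemental-formula increment on the unmodified (free-thiol) peptide:
#' \describe{
#'   \item{prenyl}{+C5H8 (68.0626 Da), heteroatom-bound dimethylallyl.}
#'   \item{geranyl}{+C10H16 (136.1252 Da), exactly two prenyl equivalents.}
#'   \item{disulfide}{-H2 per intramolecular bridge (oxidation of two Cys).}
#'   \item{met_sulfoxide}{+O per oxidized methionine (sample-preparation
#'     artifact, not precursor-encoded).}
#'   \item{cam_cys}{+C2H3NO per carboxyamidomethylated cysteine
#'     (iodoacetamide alkylation of a free thiol). Relative to the
#'     disulfide-bridged form, derivatizing a bridge is +2H (reduction) plus
#'     2 x C2H3NO = +116 Da nominal.}
#' }
#'
#' @return A data.frame with columns `name`, `delta_formula`, `sign`,
#'   `monoisotopic_delta`, `note`.
#' @export
modification_table <- function() {
  if (is.null(.mod_cache$table)) {
    path <- system.file("extdata", "modifications.tsv", package = "cyanomine",
                        mustWork = TRUE)
    tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
    tab$monoisotopic_delta <- vapply(seq_len(nrow(tab)), function(i) {
      tab$sign[i] * monoisotopic_mass(chem_formula(tab$delta_formula[i]))
    }, numeric(1))
    .mod_cache$table <- tab
  }
  .mod_cache$table
}

.mod_delta <- function(name) {
  tab <- modification_table()
  i <- match(name, tab$name)
  if (is.na(i)) stop("unknown modification: '", name, "'")
  list(formula = chem_formula(tab$delta_formula[i]), sign = tab$sign[i])
}

#' Construct a (possibly modified) peptide product
#'
#' A peptide product is a core sequence plus a topology and a multiset of
#' modifications. Invariants enforced: at most floor(nCys/2) disulfide
#' bridges; carboxyamidomethylation and bridging cannot claim the same
#' cysteines (2 x disulfide + cam_cys <= nCys); at most one sulfoxide per
#' methionine.
#'
#' @param core Amino-acid string (standard residues).
#' @param topology `"cyclic"` (default) or `"linear"`.
#' @param mods Named integer vector of modification counts, e.g.
#'   `c(prenyl = 1)` or `c(disulfide = 1, met_sulfoxide = 1)`. Names must be
#'   rows of [modification_table()].
#' @param charge Positive integer charge state for m/z reporting.
#' @return An object of class `peptide_product`.
#' @examples
#' peptide_product("GTHLYTITP", mods = c(geranyl = 1))
#' @export
peptide_product <- function(core, topology = c("cyclic", "linear"),
                            mods = integer(0), charge = 1L) {
  topology <- match.arg(topology)
  base <- peptide_formula(core, topology)  # validates the core
  if (length(mods) > 0 && is.null(names(mods))) stop("'mods' must be named")
  mods <- mods[mods != 0]
  known <- modification_table()$name
  bad <- setdiff(names(mods), known)
  if (length(bad) > 0) stop("unknown modification(s): ", paste(bad, collapse = ", "))
  if (any(mods < 0 | mods != round(mods))) {
    stop("modification counts must be non-negative integers")
  }
  n_cys <- count_residue(core, "C")
  n_met <- count_residue(core, "M")
  n_ss <- if ("disulfide" %in% names(mods)) mods[["disulfide"]] else 0L
  n_cam <- if ("cam_cys" %in% names(mods)) mods[["cam_cys"]] else 0L
  n_ox <- if ("met_sulfoxide" %in% names(mods)) mods[["met_sulfoxide"]] else 0L
  if (n_ss > floor(n_cys / 2)) {
    stop("core '", core, "' has ", n_cys, " Cys: at most ", floor(n_cys / 2),
         " disulfide bridge(s) possible")
  }
  if (2 * n_ss + n_cam > n_cys) {
    stop("disulfide bridges and carboxyamidomethylation together claim more ",
         "cysteines than core '", core, "' has (", n_cys, ")")
  }
  if (n_ox > n_met) {
    stop("core '", core, "' has ", n_met, " Met: cannot carry ", n_ox, " sulfoxide(s)")
  }
  if (!is.numeric(charge) || length(charge) != 1 || charge < 1 || charge != round(charge)) {
    stop("'charge' must be a positive integer")
  }
  structure(list(core = core, topology = topology,
                 mods = stats::setNames(as.integer(mods), names(mods)),
                 charge = as.integer(charge)),
            class = "peptide_product")
}

#' @export
print.peptide_product <- function(x, ...) {
  modtxt <- if (length(x$mods) == 0) "unmodified"
            else paste(sprintf("%s x%d", names(x$mods), x$mods), collapse = ", ")
  cat("<peptide_product> ", x$core, " (", x$topology, "; ", modtxt, ")\n", sep = "")
  f <- apply_modifications(x)
  cat("  formula ", format(f), ", [M+", x$charge, "H]", x$charge, "+ m/z ",
      sprintf("%.4f", protonated_mz(f, x$charge)), "\n", sep = "")
  invisible(x)
}

#' Elemental formula of a modified peptide product
#'
#' Applies the product's modification multiset to its base peptide formula:
#' each modification contributes its signed formula increment from
#' [modification_table()], once per instance.
#'
#' @param p A [peptide_product].
#' @return A [chem_formula] for the neutral modified product.
#' @examples
#' # disulfide-bridged macrocycle: nominal MH+ 1544
#' f <- apply_modifications(peptide_product("TLGCMNGTERCLGLP", mods = c(disulfide = 1)))
#' nominal_mz(f)
#' @export
apply_modifications <- function(p) {
  stopifnot(inherits(p, "peptide_product"))
  f <- peptide_formula(p$core, p$topology)
  for (name in names(p$mods)) {
    d <- .mod_delta(name)
    inc <- p$mods[[name]] * d$formula
    f <- if (d$sign >= 0) f + inc else f - inc
  }
  f
}

#' Monoisotopic m/z of a peptide product
#'
#' Convenience wrapper: modification algebra then protonation at the product's
#' charge state.
#'
#' @param p A [peptide_product].
#' @return Monoisotopic m/z.
#' @export
product_mz <- function(p) {
  protonated_mz(apply_modifications(p), p$charge)
}
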