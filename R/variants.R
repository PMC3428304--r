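# Variant enumeration and MS1/MS2 matching. Observed peaks are assigned to
# theoretical product variants by mass; diagnostic neutral losses in MS2
# spectra and stable-isotope label shifts annotate (never create) matches.

# Diagnostic neutral losses (Da) and the evidence flag each one sets.
.NEUTRAL_LOSSES <- c(
  isoprenoid_loss_68 = 68.0626,   # prenyl, C5H8
  isoprenoid_loss_136 = 136.1252, # geranyl (or two prenyls), C10H16
  cam_cys_loss_91 = 91.0092,      # H2N-C(=O)-CH2-SH from carbamidomethyl-Cys
  metox_loss_64 = 63.9983         # CH3SOH from methionine sulfoxide
)

#' Diagnostic neutral-loss table
#' @return Named numeric vector: evidence flag to loss mass in Da.
#' @export
neutral_loss_table <- function() .NEUTRAL_LOSSES

#' Enumerate modified variants of a cyclic core
#'
#' Builds the Cartesian product of modification counts for one core:
#' prenyl `0..max_prenyl`, geranyl `0..max_geranyl` under a combined
#' isoprenoid cap (geranyl counts as two units), disulfide `0..floor(nCys/2)`,
#' methionine sulfoxide `0..nMet`. Topology is always head-to-tail cyclic.
#' Note geranyl and two prenyls are isobaric at MS1; the variant label keeps
#' both counts so downstream reporting can say "isoprenoid x2".
#'
#' @param core Amino-acid string.
#' @param max_prenyl,max_geranyl Per-class caps (defaults 2 and 1).
#' @param isoprenoid_cap Combined cap in prenyl units (default 2).
#' @param allow_disulfide_with_isoprenoid If `FALSE`, drop variants carrying
#'   both a bridge and an isoprenoid (default `TRUE`).
#' @param charge Charge state for m/z (default 1).
#' @return A data.frame, one row per variant, in a deterministic order:
#'   `core`, `n_prenyl`, `n_geranyl`, `n_disulfide`, `n_metox`, `n_mods`,
#'   `variant` (compact label, `"unmodified"` for the bare macrocycle),
#'   `formula`, `mz`.
#' @examples
#' enumerate_variants("GTHLYTITP")[, c("variant", "mz")]
#' @export
enumerate_variants <- function(core, max_prenyl = 2, max_geranyl = 1,
                               isoprenoid_cap = 2,
                               allow_disulfide_with_isoprenoid = TRUE,
                               charge = 1L) {
  peptide_formula(core)  # validate early
  n_cys <- count_residue(core, "C")
  n_met <- count_residue(core, "M")
  grid <- expand.grid(n_prenyl = 0:max_prenyl,
                      n_geranyl = 0:max_geranyl,
                      n_disulfide = 0:(floor(n_cys / 2)),
                      n_metox = 0:n_met,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[grid$n_prenyl + 2 * grid$n_geranyl <= isoprenoid_cap, , drop = FALSE]
  if (!allow_disulfide_with_isoprenoid) {
    grid <- grid[!(grid$n_disulfide > 0 & (grid$n_prenyl + grid$n_geranyl) > 0), ,
                 drop = FALSE]
  }
  grid <- grid[order(grid$n_prenyl + grid$n_geranyl + grid$n_disulfide + grid$n_metox,
                     grid$n_prenyl, grid$n_geranyl, grid$n_disulfide, grid$n_metox), ,
               drop = FALSE]
  lab <- function(pr, ge, ss, ox) {
    parts <- c(if (pr > 0) paste0("prenyl", if (pr > 1) paste0("x", pr)),
               if (ge > 0) paste0("geranyl", if (ge > 1) paste0("x", ge)),
               if (ss > 0) paste0("disulfide", if (ss > 1) paste0("x", ss)),
               if (ox > 0) paste0("metox", if (ox > 1) paste0("x", ox)))
    if (length(parts) == 0) "unmodified" else paste(parts, collapse = "+")
  }
  n <- nrow(grid)
  variant <- character(n); fml <- character(n); mz <- numeric(n)
  for (i in seq_len(n)) {
    mods <- c(prenyl = grid$n_prenyl[i], geranyl = grid$n_geranyl[i],
              disulfide = grid$n_disulfide[i], met_sulfoxide = grid$n_metox[i])
    p <- peptide_product(core, "cyclic", mods = mods, charge = charge)
    f <- apply_modifications(p)
    variant[i] <- lab(grid$n_prenyl[i], grid$n_geranyl[i],
                      grid$n_disulfide[i], grid$n_metox[i])
    fml[i] <- format(f)
    mz[i] <- protonated_mz(f, charge)
  }
  data.frame(core = core, grid,
             n_mods = grid$n_prenyl + grid$n_geranyl + grid$n_disulfide + grid$n_metox,
             variant = variant, formula = fml, mz = mz,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Construct a peak list
#'
#' @param mz,intensity Numeric vectors of equal length; m/z must be positive,
#'   intensities non-negative. Peaks are stored sorted by m/z.
#' @param level `"MS1"` or `"MS2"`.
#' @param precursor_mz Precursor m/z, required for MS2.
#' @param source_id Provenance string.
#' @return An object of class `peak_list`: a data.frame `peaks` plus
#'   attributes `level`, `precursor_mz`, `source_id`.
#' @export
peak_list <- function(mz, intensity = rep(1, length(mz)),
                      level = c("MS1", "MS2"), precursor_mz = NULL,
                      source_id = NA_character_) {
  level <- match.arg(level)
  if (length(mz) != length(intensity)) stop("'mz' and 'intensity' lengths differ")
  if (any(!is.finite(mz)) || any(mz <= 0)) stop("all m/z values must be positive and finite")
  if (any(!is.finite(intensity)) || any(intensity < 0)) {
    stop("all intensities must be non-negative and finite")
  }
  if (level == "MS2" && is.null(precursor_mz)) {
    stop("MS2 peak lists require 'precursor_mz'")
  }
  ord <- order(mz)
  structure(list(peaks = data.frame(mz = mz[ord], intensity = intensity[ord]),
                 level = level,
                 precursor_mz = precursor_mz,
                 source_id = source_id),
            class = "peak_list")
}

#' @export
print.peak_list <- function(x, ...) {
  cat("<peak_list> ", x$level, ", ", nrow(x$peaks), " peaks",
      if (!is.null(x$precursor_mz)) sprintf(", precursor m/z %.4f", x$precursor_mz),
      if (!is.na(x$source_id)) paste0(" [", x$source_id, "]"), "\n", sep = "")
  invisible(x)
}

#' Match theoretical variants against an MS1 peak list
#'
#' Reports every (variant, peak) pair whose m/z difference is within
#' tolerance. Per observed peak, candidates are ranked by |delta| and ties
#' broken by parsimony (fewer modification instances), then by variant
#' label, so the ordering is a deterministic function of the inputs alone.
#'
#' @param variants Output of [enumerate_variants()] (rows from several cores
#'   may be concatenated with `rbind`).
#' @param peaks A `peak_list` of level MS1.
#' @param tol_mda Matching tolerance in mDa (default 20, high-accuracy mode;
#'   use 300 for ion-trap data).
#' @return A data.frame of matches: `peak_mz`, `intensity`, `core`,
#'   `variant`, `theoretical_mz`, `delta_mda` (observed minus theoretical),
#'   `n_mods`, `rank` (1 = best for that peak).
#' @export
match_peaks <- function(variants, peaks, tol_mda = 20) {
  stopifnot(is.data.frame(variants), inherits(peaks, "peak_list"))
  if (peaks$level != "MS1") stop("'peaks' must be an MS1 peak list")
  if (!is.numeric(tol_mda) || tol_mda <= 0) stop("'tol_mda' must be positive")
  empty <- data.frame(peak_mz = numeric(), intensity = numeric(),
                      core = character(), variant = character(),
                      theoretical_mz = numeric(), delta_mda = numeric(),
                      n_mods = integer(), rank = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(peaks$peaks) == 0 || nrow(variants) == 0) return(empty)
  tol <- tol_mda / 1000
  out <- list()
  for (i in seq_len(nrow(peaks$peaks))) {
    obs <- peaks$peaks$mz[i]
    d <- obs - variants$mz
    hit <- which(abs(d) <= tol)
    if (length(hit) == 0) next
    cand <- data.frame(peak_mz = obs, intensity = peaks$peaks$intensity[i],
                       core = variants$core[hit], variant = variants$variant[hit],
                       theoretical_mz = variants$mz[hit],
                       delta_mda = d[hit] * 1000,
                       n_mods = variants$n_mods[hit],
                       stringsAsFactors = FALSE)
    cand <- cand[order(abs(cand$delta_mda), cand$n_mods, cand$core, cand$variant), ,
                 drop = FALSE]
    cand$rank <- seq_len(nrow(cand))
    out[[length(out) + 1]] <- cand
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Detect diagnostic neutral losses in an MS2 spectrum
#'
#' Scans a fragment spectrum for the losses diagnostic of cyanobactin
#' modifications: 68 / 136 Da (isoprenoid units), 91 Da (the
#' H2N-C(=O)-CH2-SH fragment of carbamidomethylated cysteine) and 64 Da
#' (CH3SOH from methionine sulfoxide). A flag is set when a fragment lies
#' within tolerance of precursor minus loss and is at least
#' `min_rel_intensity` of the base peak.
#'
#' @param ms2 A `peak_list` of level MS2 (with `precursor_mz`).
#' @param tol Absolute m/z tolerance in Da (default 0.3, ion-trap scale).
#' @param min_rel_intensity Relative intensity floor (default 0.05).
#' @return Character vector of evidence flags (subset of
#'   `names(neutral_loss_table())`).
#' @export
detect_neutral_losses <- function(ms2, tol = 0.3, min_rel_intensity = 0.05) {
  stopifnot(inherits(ms2, "peak_list"))
  if (ms2$level != "MS2" || is.null(ms2$precursor_mz)) {
    stop("'ms2' must be an MS2 peak list with a precursor m/z")
  }
  if (nrow(ms2$peaks) == 0) return(character(0))
  base <- max(ms2$peaks$intensity)
  floor_abs <- if (base > 0) min_rel_intensity * base else 0
  found <- vapply(.NEUTRAL_LOSSES, function(L) {
    target <- ms2$precursor_mz - L
    any(abs(ms2$peaks$mz - target) <= tol & ms2$peaks$intensity >= floor_abs)
  }, logical(1))
  names(.NEUTRAL_LOSSES)[found]
}

#' Check a match against a stable-isotope label shift
#'
#' Predicts the labeled m/z of a matched variant (theoretical m/z plus the
#' full-label shift of its formula) and compares with the observed labeled
#' peak; also counts the labeled atoms from the observed shift. The label
#' shift confirms elemental content, e.g. a +4 Da shift under 34S counts two
#' sulfur atoms.
#'
#' @param formula The matched variant's [chem_formula] (or a formula string).
#' @param theoretical_mz Its unlabeled theoretical m/z.
#' @param labeled_observed_mz Observed m/z of the labeled compound.
#' @param label An [isotope_label].
#' @param tol Consistency tolerance in Da (default 0.3).
#' @param z Charge (default 1).
#' @return A list: `predicted_mz`, `observed_mz`, `difference`
#'   (observed minus predicted, Da), `n_atoms_expected`, `n_atoms_inferred`,
#'   `consistent`.
#' @export
verify_labels <- function(formula, theoretical_mz, labeled_observed_mz, label,
                          tol = 0.3, z = 1L) {
  f <- chem_formula(formula)
  stopifnot(inherits(label, "isotope_label"))
  shift <- isotope_shift(f, label)
  predicted <- theoretical_mz + shift / z
  diff <- labeled_observed_mz - predicted
  observed_shift <- (labeled_observed_mz - theoretical_mz) * z
  inf <- if (observed_shift >= 0) {
    infer_atom_count(observed_shift, label)
  } else {
    list(n_atoms = NA_integer_, residual = NA_real_, consistent = FALSE)
  }
  list(predicted_mz = predicted,
       observed_mz = labeled_observed_mz,
       difference = diff,
       n_atoms_expected = as.integer(f$counts[[label$element]]),
       n_atoms_inferred = inf$n_atoms,
       consistent = abs(diff) <= tol)
}
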