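#' Enumerate elemental formulas matching a target mass
#'
#' Exhaustive search over integer element compositions whose monoisotopic
#' mass lies within a tolerance of a target — the standard way to propose
#' compositions for an unexplained mass difference (e.g. an 84.0311 Da
#' adduct on a cyclic peptide). Candidates pass a chemical plausibility
#' filter before ranking:
#' \itemize{
#'   \item ring-plus-double-bond equivalent RDBE = C - H/2 + N/2 + 1 at least
#'     -0.5 (half-integral values correspond to even-electron species);
#'   \item hydrogen count at most 2C + 2 + N (saturation bound).
#' }
#'
#' @param target Target neutral mass, Da.
#' @param tol_mda Tolerance in mDa (default 50).
#' @param elements Character vector of elements to enumerate over, a subset
#'   of C, H, N, O, S. Default `c("C", "H", "O")`.
#' @param max_counts Per-element maximum counts: either a single integer
#'   applied to every element, a named vector, or `NULL` (default) for the
#'   natural bound floor(target + tol over the element's mass).
#' @return A data.frame ordered by |delta|, with one row per candidate:
#'   element-count columns, `formula` (Hill string), `mass` (Da), and
#'   `delta_mda` (signed candidate minus target, mDa).
#' @examples
#' fs <- formula_search(84.0311, tol_mda = 50, elements = c("C", "H", "O"))
#' fs$formula  # contains "C4H4O2" and "C5H8O"
#' @export
formula_search <- function(target, tol_mda = 50, elements = c("C", "H", "O"),
                           max_counts = NULL) {
  if (!is.numeric(target) || length(target) != 1 || !is.finite(target) || target <= 0) {
    stop("'target' must be a single positive mass in Da")
  }
  if (!is.numeric(tol_mda) || length(tol_mda) != 1 || tol_mda <= 0) {
    stop("'tol_mda' must be a positive tolerance in mDa")
  }
  elements <- unique(elements)
  if (length(elements) == 0) stop("'elements' must name at least one element")
  bad <- setdiff(elements, names(.ELEMENT_MASS))
  if (length(bad) > 0) stop("unsupported element(s): ", paste(bad, collapse = ", "))

  tol <- tol_mda / 1000
  natural <- floor((target + tol) / .ELEMENT_MASS[elements])
  if (is.null(max_counts)) {
    bounds <- natural
  } else if (length(max_counts) == 1 && is.null(names(max_counts))) {
    bounds <- stats::setNames(rep(max_counts, length(elements)), elements)
  } else {
    missing_el <- setdiff(elements, names(max_counts))
    if (length(missing_el) > 0) {
      stop("'max_counts' lacks bound(s) for: ", paste(missing_el, collapse = ", "))
    }
    bounds <- max_counts[elements]
  }
  if (any(!is.finite(bounds)) || any(bounds < 0)) stop("bounds must be finite and non-negative")
  bounds <- pmin(bounds, natural)  # counts above the natural bound cannot match

  grid <- do.call(expand.grid, c(lapply(bounds, function(b) 0:b),
                                 list(KEEP.OUT.ATTRS = FALSE)))
  mass <- as.numeric(as.matrix(grid) %*% .ELEMENT_MASS[elements])
  keep <- abs(mass - target) <= tol & rowSums(grid) > 0
  grid <- grid[keep, , drop = FALSE]
  mass <- mass[keep]

  getc <- function(el) if (el %in% elements) grid[[el]] else rep(0, nrow(grid))
  rdbe <- getc("C") - getc("H") / 2 + getc("N") / 2 + 1
  plausible <- rdbe >= -0.5 & (rdbe %% 0.5 == 0) &
    getc("H") <= 2 * getc("C") + 2 + getc("N")
  grid <- grid[plausible, , drop = FALSE]
  mass <- mass[plausible]
  rdbe <- rdbe[plausible]

  res <- data.frame(grid,
                    formula = vapply(seq_len(nrow(grid)), function(i) {
                      format(chem_formula(stats::setNames(as.numeric(grid[i, elements]), elements)))
                    }, character(1)),
                    mass = mass,
                    rdbe = rdbe,
                    delta_mda = (mass - target) * 1000,
                    stringsAsFactors = FALSE)
  res <- res[order(abs(res$delta_mda), res$formula), , drop = FALSE]
  rownames(res) <- NULL
  res
}
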