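# Independent oracles, deliberately naive, used to cross-check the package's
# optimized paths.

# Published monoisotopic residue masses (dehydrated monomers), standard
# reference values to 5 decimals.
REFERENCE_RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

# Exhaustive nested-loop formula search over C/H/N/O/S, no vectorization.
oracle_formula_search <- function(target, tol_mda, elements, bound) {
  masses <- c(C = 12.0, H = 1.0078250319, N = 14.0030740052,
              O = 15.9949146221, S = 31.9720706912)
  res <- list()
  counts <- stats::setNames(rep(0L, 5), names(masses))
  els <- names(masses)
  rec <- function(i, cur) {
    if (i > length(els)) {
      m <- sum(cur * masses)
      if (sum(cur) > 0 && abs(m - target) <= tol_mda / 1000) {
        rdbe <- cur[["C"]] - cur[["H"]] / 2 + cur[["N"]] / 2 + 1
        if (rdbe >= -0.5 && rdbe %% 0.5 == 0 &&
            cur[["H"]] <= 2 * cur[["C"]] + 2 + cur[["N"]]) {
          res[[length(res) + 1]] <<- cur
        }
      }
      return(invisible())
    }
    el <- els[i]
    top <- if (el %in% elements) bound else 0L
    for (k in 0:top) { cur[[el]] <- k; rec(i + 1, cur) }
  }
  rec(1, counts)
  if (length(res) == 0) return(character(0))
  sort(vapply(res, function(cur) {
    format(chem_formula(cur[cur > 0]))
  }, character(1)))
}

# Character-by-character sliding-window motif scan.
oracle_scan_motif <- function(aa, pattern, max_mismatch = 0) {
  s <- strsplit(aa, "")[[1]]; p <- strsplit(pattern, "")[[1]]
  hits <- integer(0)
  if (length(p) > length(s)) return(hits)
  for (start in 1:(length(s) - length(p) + 1)) {
    mm <- 0
    for (j in seq_along(p)) {
      cj <- s[start + j - 1]
      ok <- if (p[j] == "x") cj != "X" else cj == p[j]
      if (!ok) mm <- mm + 1
    }
    if (mm <= max_mismatch) hits <- c(hits, start)
  }
  hits
}

# Per-residue element counting, independent of the chem_formula machinery.
ORACLE_N_PER_RESIDUE <- c(
  G = 1, A = 1, S = 1, P = 1, V = 1, T = 1, C = 1, L = 1, I = 1, N = 2,
  D = 1, Q = 2, K = 2, E = 1, M = 1, H = 3, F = 1, R = 4, Y = 1, W = 2
)
oracle_nitrogen_count <- function(core) {
  sum(ORACLE_N_PER_RESIDUE[strsplit(core, "")[[1]]])
}

random_aa <- function(n, alphabet = names(REFERENCE_RESIDUE_MASS)) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
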