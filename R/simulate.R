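# Seeded forward model: precursor genes -> clone library -> peak lists, with
# a truth table, so mining and matching can be scored without instrument
# data. All generation is a pure function of (seed, config).

# Background residue alphabet for random cores and leaders: Cys and Met are
# excluded and planted explicitly, so the disulfide/sulfoxide ground truth is
# exactly what the generator decided.
.SIM_ALPHABET <- setdiff(names(.RESIDUE_COMPOSITION), c("C", "M"))

#' Simulation configuration
#'
#' Defaults emulate the observed shape of a natural piricyclamide clone
#' library and strain collection: 19 unique cores among 122 clones, core
#' lengths 7-22 aa with every core ending in proline, roughly one core in
#' ten carrying the double-cysteine (disulfide) pattern, one in five a
#' methionine, and an isoprenoid spectrum of about half unmodified, a
#' quarter prenylated, a quarter geranylated.
#'
#' @param seed Integer seed (mandatory; all generation derives from it).
#' @param n_precursors Number of unique precursor cores (default 19).
#' @param n_clones Total clones in the library (default 122).
#' @param core_length_range Core length range in aa (default `c(7, 22)`).
#' @param frac_disulfide Fraction of cores given a Cys pair (default 0.1).
#' @param frac_met Fraction of cores given a Met (default 0.2).
#' @param frac_metox Probability that a Met-containing product is oxidized
#'   to the sulfoxide during sample handling (default 0.3).
#' @param mod_probs Probabilities for the isoprenoid state of each product:
#'   named vector over `none`, `prenyl`, `geranyl` (default 0.5/0.25/0.25).
#' @param zipf_exponent Clone-abundance skew: clone counts follow rank^(-s)
#'   (default 1; 0 gives near-uniform counts).
#' @param mz_error_sd_mda Gaussian m/z error on planted MS1 peaks, mDa
#'   (default 5).
#' @param n_noise_peaks Uniform decoy peaks added inside the instrument scan
#'   range m/z 300-2200 (default 20).
#' @param end_in_proline Force cores to end in P, as every catalogued core
#'   does (default TRUE).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_precursors = 19,
                       n_clones = 122,
                       core_length_range = c(7, 22),
                       frac_disulfide = 0.1,
                       frac_met = 0.2,
                       frac_metox = 0.3,
                       mod_probs = c(none = 0.5, prenyl = 0.25, geranyl = 0.25),
                       zipf_exponent = 1,
                       mz_error_sd_mda = 5,
                       n_noise_peaks = 20,
                       end_in_proline = TRUE) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 || seed != round(seed)) {
    stop("'seed' is mandatory and must be a single integer")
  }
  stopifnot(n_precursors >= 1, n_clones >= n_precursors,
            length(core_length_range) == 2,
            core_length_range[1] >= 1,
            core_length_range[1] <= core_length_range[2],
            frac_disulfide >= 0, frac_disulfide <= 1,
            frac_met >= 0, frac_met <= 1,
            frac_metox >= 0, frac_metox <= 1,
            mz_error_sd_mda >= 0, n_noise_peaks >= 0)
  if (!all(c("none", "prenyl", "geranyl") %in% names(mod_probs))) {
    stop("'mod_probs' must name none, prenyl and geranyl")
  }
  mod_probs <- mod_probs / sum(mod_probs)
  structure(list(seed = as.integer(seed), n_precursors = n_precursors,
                 n_clones = n_clones, core_length_range = core_length_range,
                 frac_disulfide = frac_disulfide, frac_met = frac_met,
                 frac_metox = frac_metox, mod_probs = mod_probs,
                 zipf_exponent = zipf_exponent,
                 mz_error_sd_mda = mz_error_sd_mda,
                 n_noise_peaks = n_noise_peaks,
                 end_in_proline = end_in_proline),
            class = "sim_config")
}

# Uniform choice among synonymous codons for each residue.
.codon_choices <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- Biostrings::GENETIC_CODE
      tab <<- split(names(gc), unname(gc))
    }
    tab
  }
})

.reverse_translate <- function(aa) {
  choices <- .codon_choices()
  paste(vapply(strsplit(aa, "")[[1]], function(r) {
    opts <- choices[[r]]
    opts[sample.int(length(opts), 1)]
  }, character(1)), collapse = "")
}

.random_core <- function(len, with_cys_pair, with_met, end_in_proline) {
  res <- sample(.SIM_ALPHABET, len, replace = TRUE)
  if (end_in_proline) res[len] <- "P"
  interior <- seq_len(max(len - 1, 1))
  plant <- function(res, what, k) {
    pos <- sample(interior, k)
    res[pos] <- what
    res
  }
  if (with_met && len >= 2) res <- plant(res, "M", 1)
  if (with_cys_pair && len >= 3) {
    free <- setdiff(interior, which(res == "M"))
    pos <- sample(free, 2)
    res[pos] <- "C"
  }
  paste(res, collapse = "")
}

.fill_motif <- function(pattern) {
  p <- strsplit(pattern, "")[[1]]
  p[p == "x"] <- sample(.SIM_ALPHABET, sum(p == "x"), replace = TRUE)
  paste(p, collapse = "")
}

.random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                 collapse = "")

#' Generate one synthetic precursor gene
#'
#' Emits a precursor gene with the canonical architecture — random N-terminal
#' padding, an exact leader-motif instance, the given core, the recognition
#' motif FAGD, a short tail — reverse-translated with uniform synonymous
#' codons, embedded in random flanking DNA on a random strand, with an
#' in-frame stop closing the ORF.
#'
#' @param core Amino-acid core to plant.
#' @param seed Optional integer; when given, `set.seed(seed)` is called first
#'   so the gene is a pure function of (seed, core). Omit to draw from the
#'   caller's RNG stream.
#' @param leader_pattern Leader motif whose exact instance is planted
#'   (default `"KKNxxPxxxxPVxR"`).
#' @param flank_len Length of each random DNA flank (default 30).
#' @return A list: `dna`, `strand`, `core`, `orf_aa` (the designed precursor
#'   protein), `core_nt_start`/`core_nt_end` (0-based half-open forward
#'   coordinates of the core codons).
#' @export
gen_precursor_gene <- function(core, seed = NULL,
                               leader_pattern = "KKNxxPxxxxPVxR",
                               flank_len = 30) {
  peptide_formula(core)  # validate
  if (!is.null(seed)) set.seed(as.integer(seed))
  pad <- paste(sample(.SIM_ALPHABET, sample(3:6, 1), replace = TRUE), collapse = "")
  tail_aa <- paste(sample(.SIM_ALPHABET, sample(2:5, 1), replace = TRUE), collapse = "")
  leader <- .fill_motif(leader_pattern)
  prot <- paste0(pad, leader, core, "FAGD", tail_aa)
  orf_dna <- .reverse_translate(prot)
  gene_fwd <- paste0(.random_dna(flank_len), "TAA", orf_dna, "TAA",
                     .random_dna(flank_len))
  # core codon span on the forward-built gene (0-based half-open)
  off <- flank_len + 3 + 3 * (nchar(pad) + nchar(leader))
  core_start <- off
  core_end <- off + 3 * nchar(core)
  strand <- sample(c("+", "-"), 1)
  if (strand == "+") {
    dna <- gene_fwd
  } else {
    dna <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(gene_fwd)))
    L <- nchar(gene_fwd)
    tmp <- core_start
    core_start <- L - core_end
    core_end <- L - tmp
  }
  list(dna = dna, strand = strand, core = core, orf_aa = prot,
       core_nt_start = core_start, core_nt_end = core_end)
}

# Largest-remainder allocation of n_clones over rank^(-s) weights, at least
# one clone per core; deterministic.
.allocate_clones <- function(n_cores, n_clones, s) {
  w <- (seq_len(n_cores))^(-s)
  w <- w / sum(w)
  extra <- n_clones - n_cores
  base <- floor(extra * w)
  rem <- extra - sum(base)
  frac <- extra * w - base
  if (rem > 0) {
    give <- order(-frac, seq_len(n_cores))[seq_len(rem)]
    base[give] <- base[give] + 1
  }
  as.integer(1 + base)
}

#' Generate a synthetic precursor clone library
#'
#' Draws unique cores per the configuration, assigns each a modification
#' state (disulfide bridged when a Cys pair was planted; isoprenoid state
#' from `mod_probs`; sulfoxide with probability `frac_metox` when a Met is
#' present), allocates clone counts by the configured abundance law, and
#' instantiates one gene per core replicated over its clones.
#'
#' @param cfg A [sim_config()].
#' @return A list: `fasta` (named character vector, one DNA record per
#'   clone), `truth` (data.frame, one row per unique core: `core_id`,
#'   `core`, `n_clones`, modification counts, `variant` label, `formula`,
#'   `mz`, `strand`, `core_nt_start`, `core_nt_end`).
#' @export
gen_clone_library <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  lmin <- cfg$core_length_range[1]; lmax <- cfg$core_length_range[2]
  n_space <- sum(vapply(lmin:lmax, function(l) length(.SIM_ALPHABET)^max(l - 1, 0),
                        numeric(1)))
  if (cfg$n_precursors > n_space) stop("more unique cores requested than the length space holds")
  set.seed(cfg$seed)
  cores <- character(0)
  planted_ss <- logical(0); planted_met <- logical(0)
  while (length(cores) < cfg$n_precursors) {
    len <- sample(lmin:lmax, 1)
    ss <- stats::runif(1) < cfg$frac_disulfide && len >= 4
    met <- stats::runif(1) < cfg$frac_met && len >= 3
    cc <- .random_core(len, ss, met, cfg$end_in_proline)
    if (cc %in% cores) next
    cores <- c(cores, cc)
    planted_ss <- c(planted_ss, count_residue(cc, "C") >= 2)
    planted_met <- c(planted_met, count_residue(cc, "M") >= 1)
  }
  iso <- sample(names(cfg$mod_probs), cfg$n_precursors, replace = TRUE,
                prob = cfg$mod_probs)
  n_prenyl <- as.integer(iso == "prenyl")
  n_geranyl <- as.integer(iso == "geranyl")
  n_disulfide <- as.integer(planted_ss)
  n_metox <- as.integer(planted_met & stats::runif(cfg$n_precursors) < cfg$frac_metox)
  counts <- .allocate_clones(cfg$n_precursors, cfg$n_clones, cfg$zipf_exponent)

  truth <- data.frame(core_id = sprintf("core%02d", seq_len(cfg$n_precursors)),
                      core = cores, n_clones = counts,
                      n_prenyl = n_prenyl, n_geranyl = n_geranyl,
                      n_disulfide = n_disulfide, n_metox = n_metox,
                      stringsAsFactors = FALSE)
  gene <- vector("list", cfg$n_precursors)
  for (i in seq_len(cfg$n_precursors)) gene[[i]] <- gen_precursor_gene(cores[i])
  truth$strand <- vapply(gene, `[[`, character(1), "strand")
  truth$core_nt_start <- vapply(gene, `[[`, numeric(1), "core_nt_start")
  truth$core_nt_end <- vapply(gene, `[[`, numeric(1), "core_nt_end")
  fv <- character(cfg$n_precursors); mz <- numeric(cfg$n_precursors)
  variant <- character(cfg$n_precursors)
  for (i in seq_len(cfg$n_precursors)) {
    mods <- c(prenyl = n_prenyl[i], geranyl = n_geranyl[i],
              disulfide = n_disulfide[i], met_sulfoxide = n_metox[i])
    p <- peptide_product(cores[i], "cyclic", mods = mods)
    f <- apply_modifications(p)
    fv[i] <- format(f)
    mz[i] <- protonated_mz(f)
    parts <- c(if (n_prenyl[i]) "prenyl", if (n_geranyl[i]) "geranyl",
               if (n_disulfide[i]) "disulfide", if (n_metox[i]) "metox")
    variant[i] <- if (length(parts) == 0) "unmodified" else paste(parts, collapse = "+")
  }
  truth$variant <- variant
  truth$formula <- fv
  truth$mz <- mz

  fasta <- character(0)
  for (i in seq_len(cfg$n_precursors)) {
    ids <- sprintf("%s_clone%03d", truth$core_id[i], seq_len(counts[i]))
    fasta <- c(fasta, stats::setNames(rep(gene[[i]]$dna, counts[i]), ids))
  }
  list(fasta = fasta, truth = truth)
}

#' Generate MS1 and MS2 peak lists from a truth table
#'
#' Plants one MS1 peak per true product variant at its theoretical m/z plus
#' Gaussian error, adds uniform decoy peaks inside the instrument scan range
#' (m/z 300-2200), and emits per-product MS2 lists containing the diagnostic
#' neutral-loss fragments implied by the planted modifications (68 for a
#' prenyl, 68 and 136 for a geranyl, 64 for a sulfoxide) plus random
#' fragments.
#'
#' @param truth Truth table from [gen_clone_library()].
#' @param cfg The same [sim_config()]. The RNG is seeded from
#'   `cfg$seed + 1` so peak noise is independent of library generation.
#' @return A list: `ms1` (a `peak_list`), `ms2` (named list of `peak_list`s,
#'   one per `core_id`).
#' @export
gen_peaklists <- function(truth, cfg) {
  stopifnot(is.data.frame(truth), nrow(truth) > 0, inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  sd_da <- cfg$mz_error_sd_mda / 1000
  obs <- truth$mz + stats::rnorm(nrow(truth), 0, sd_da)
  inten <- truth$n_clones * stats::rlnorm(nrow(truth), log(1000), 0.4)
  mz_all <- obs; int_all <- inten
  if (cfg$n_noise_peaks > 0) {
    mz_all <- c(mz_all, stats::runif(cfg$n_noise_peaks, 300, 2200))
    int_all <- c(int_all, stats::rlnorm(cfg$n_noise_peaks, log(100), 0.6))
  }
  ms1 <- peak_list(mz_all, int_all, level = "MS1", source_id = "synthetic_ms1")

  losses <- neutral_loss_table()
  ms2 <- stats::setNames(vector("list", nrow(truth)), truth$core_id)
  for (i in seq_len(nrow(truth))) {
    prec <- obs[i]
    frag_mz <- numeric(0)
    if (truth$n_prenyl[i] > 0) frag_mz <- c(frag_mz, prec - losses[["isoprenoid_loss_68"]])
    if (truth$n_geranyl[i] > 0) {
      frag_mz <- c(frag_mz, prec - losses[["isoprenoid_loss_68"]],
                   prec - losses[["isoprenoid_loss_136"]])
    }
    if (truth$n_metox[i] > 0) frag_mz <- c(frag_mz, prec - losses[["metox_loss_64"]])
    frag_int <- stats::runif(length(frag_mz), 0.5, 1)
    n_rand <- 5
    lo <- max(300, prec - 700)
    rand_mz <- stats::runif(n_rand, lo, prec - 1)
    frag_mz <- c(frag_mz, rand_mz)
    frag_int <- c(frag_int, stats::runif(n_rand, 0.05, 0.3))
    ms2[[i]] <- peak_list(frag_mz, frag_int * 1000, level = "MS2",
                          precursor_mz = prec, source_id = truth$core_id[i])
  }
  list(ms1 = ms1, ms2 = ms2)
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: clone library plus peak lists from one config.
#'
#' @param cfg A [sim_config()].
#' @return A list: `fasta`, `truth`, `ms1`, `ms2`.
#' @export
simulate_dataset <- function(cfg) {
  lib <- gen_clone_library(cfg)
  pk <- gen_peaklists(lib$truth, cfg)
  c(lib, pk)
}
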