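# Precursor-gene mining: cyanobactin precursors are short (~50 aa) proteins
# with a conserved N-terminal leader, a hypervariable core (the future
# macrocycle) and a short C-terminal recognition region. Mining scans all six
# reading frames for the leader motif and cuts the core out between the
# leader end and the first downstream recognition motif.

.check_dna <- function(dna) {
  if (!is.character(dna) || length(dna) != 1) stop("'dna' must be a single string")
  dna <- toupper(dna)
  if (grepl("[^ACGTN]", dna)) {
    bad <- unique(strsplit(gsub("[ACGTN]", "", dna), "")[[1]])
    stop("sequence contains characters outside {A,C,G,T,N}: ",
         paste(bad, collapse = ", "))
  }
  dna
}

#' Translate a DNA sequence in all six reading frames
#'
#' Translates both strands in all three frame offsets with the standard
#' genetic code and reports the amino-acid segments between stop codons.
#' There is no start-codon requirement: mined sequences may be amplicon
#' fragments. Codons containing N translate to X, which never satisfies a
#' motif position.
#'
#' @param dna Nucleotide string over \{A,C,G,T,N\} (case-insensitive).
#' @param min_len Minimum segment length in aa (default 30; the precursor
#'   proteins themselves are ~48-53 aa).
#' @return A data.frame with one row per segment: `strand` (`+`/`-`),
#'   `frame` (0-2), `aa` (segment sequence), and `nt_start`/`nt_end`
#'   (0-based half-open, always forward-strand coordinates).
#' @examples
#' translate_six_frames("ATGGGTTAA", min_len = 1)
#' @export
translate_six_frames <- function(dna, min_len = 30) {
  dna <- .check_dna(dna)
  L <- nchar(dna)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") dna else as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(dna)))
    for (frame in 0:2) {
      n_codons <- (nchar(s) - frame) %/% 3
      if (n_codons < 1) next
      sub <- substr(s, frame + 1, frame + 3 * n_codons)
      aa <- as.character(Biostrings::translate(
        Biostrings::DNAString(sub), if.fuzzy.codon = "X", no.init.codon = TRUE))
      segs <- gregexpr("[^*]+", aa)[[1]]
      if (segs[1] == -1) next
      lens <- attr(segs, "match.length")
      for (k in seq_along(segs)) {
        if (lens[k] < min_len) next
        aa_start <- segs[k]  # 1-based within this frame's translation
        seg <- substr(aa, aa_start, aa_start + lens[k] - 1)
        start_local <- frame + 3 * (aa_start - 1)  # 0-based on this strand
        end_local <- start_local + 3 * lens[k]
        if (strand == "+") {
          nt_start <- start_local; nt_end <- end_local
        } else {
          nt_start <- L - end_local; nt_end <- L - start_local
        }
        out[[length(out) + 1]] <- data.frame(
          strand = strand, frame = frame, aa = seg,
          nt_start = nt_start, nt_end = nt_end, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(strand = character(), frame = integer(), aa = character(),
                      nt_start = integer(), nt_end = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Scan a protein sequence for a motif with mismatches
#'
#' Sliding-window motif scan. Lowercase `x` in the pattern is a wildcard
#' matching any standard residue; mismatches are counted only at non-wildcard
#' positions. `X` (unknown residue, e.g. from an N-containing codon) never
#' matches any motif position, wildcards included.
#'
#' @param aa Amino-acid string.
#' @param pattern Motif, e.g. the cyanobactin leader anchor
#'   `"KKNxxPxxxxPVxR"`.
#' @param max_mismatch Maximum substitutions tolerated at non-wildcard
#'   positions (default 0).
#' @return Integer vector of 1-based match start positions (possibly
#'   overlapping); empty when the pattern is longer than the sequence.
#' @examples
#' scan_motif("AAKKNGGPGGGGPVGRAA", "KKNxxPxxxxPVxR")
#' @export
scan_motif <- function(aa, pattern, max_mismatch = 0) {
  if (!is.character(aa) || length(aa) != 1) stop("'aa' must be a single string")
  if (!is.character(pattern) || length(pattern) != 1 || !nzchar(pattern)) {
    stop("'pattern' must be a non-empty motif string")
  }
  if (max_mismatch < 0) stop("'max_mismatch' must be >= 0")
  s <- strsplit(aa, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  n <- length(s); m <- length(p)
  if (m > n) return(integer(0))
  nw <- n - m + 1
  mism <- integer(nw)
  for (j in seq_len(m)) {
    win <- s[j:(j + nw - 1)]
    bad <- if (p[j] == "x") win == "X" else win != p[j]
    mism <- mism + bad
  }
  which(mism <= max_mismatch)
}

#' Extract the core peptide from a precursor ORF
#'
#' Given a leader-motif match, the core is the segment strictly between the
#' end of the leader motif and the start of the first downstream recognition
#' motif. All cores catalogued to date sit flush against both anchors and end
#' in proline immediately before the recognition region.
#'
#' @param orf_aa Amino-acid sequence of the ORF segment.
#' @param leader_match 1-based start position of the leader-motif match.
#' @param leader_pattern The leader motif that was matched (its length fixes
#'   the cut point). Default `"KKNxxPxxxxPVxR"`.
#' @param recognition_pattern C-terminal recognition motif (default
#'   `"FAGD"`).
#' @param recognition_max_mismatch Mismatches tolerated in the recognition
#'   motif (default 1).
#' @param core_length_window Acceptable core lengths in aa, default
#'   `c(5, 30)`; extractions outside it are rejected.
#' @return A list: `status` (`"ok"`, `"no_recognition"` or `"length"`) and,
#'   when ok, `core` plus 1-based inclusive `leader_span`, `core_span`,
#'   `recognition_span` on `orf_aa`.
#' @export
extract_core <- function(orf_aa, leader_match,
                         leader_pattern = "KKNxxPxxxxPVxR",
                         recognition_pattern = "FAGD",
                         recognition_max_mismatch = 1,
                         core_length_window = c(5, 30)) {
  leader_end <- leader_match + nchar(leader_pattern) - 1
  if (leader_end > nchar(orf_aa)) stop("leader match extends past the sequence end")
  downstream <- substr(orf_aa, leader_end + 1, nchar(orf_aa))
  rec <- scan_motif(downstream, recognition_pattern, recognition_max_mismatch)
  if (length(rec) == 0) return(list(status = "no_recognition"))
  rec_start <- leader_end + rec[1]  # position on orf_aa
  core <- substr(orf_aa, leader_end + 1, rec_start - 1)
  if (nchar(core) < core_length_window[1] || nchar(core) > core_length_window[2]) {
    return(list(status = "length", core = core))
  }
  list(status = "ok", core = core,
       leader_span = c(leader_match, leader_end),
       core_span = c(leader_end + 1, rec_start - 1),
       recognition_span = c(rec_start, rec_start + nchar(recognition_pattern) - 1))
}

#' Mine precursor genes from DNA sequences
#'
#' Full mining pass: six-frame translation, leader-motif scan, core
#' extraction and classification, over a set of sequences.
#'
#' @param sequences Named character vector of DNA sequences (names become
#'   `source_id`), or a `Biostrings::DNAStringSet`.
#' @param leader_pattern,leader_max_mismatch Leader motif and its mismatch
#'   budget (defaults `"KKNxxPxxxxPVxR"`, 2).
#' @param recognition_pattern,recognition_max_mismatch Recognition motif and
#'   budget (defaults `"FAGD"`, 1).
#' @param min_orf_len Minimum translated segment length in aa (default 30).
#' @param core_length_window Acceptable core length range (default
#'   `c(5, 30)`).
#' @return A data.frame of precursor records, one per accepted extraction:
#'   `source_id`, `strand`, `frame`, `orf_aa`, `nt_start`, `nt_end`
#'   (0-based half-open forward coordinates of the ORF segment),
#'   `leader_start`, `leader_end`, `core_start`, `core_end`,
#'   `recognition_start`, `recognition_end` (1-based inclusive on `orf_aa`),
#'   `core`, and the [classify_core()] flags.
#' @export
mine_precursors <- function(sequences,
                            leader_pattern = "KKNxxPxxxxPVxR",
                            leader_max_mismatch = 2,
                            recognition_pattern = "FAGD",
                            recognition_max_mismatch = 1,
                            min_orf_len = 30,
                            core_length_window = c(5, 30)) {
  if (inherits(sequences, "DNAStringSet")) {
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  }
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    stop("'sequences' must be named (names become source ids)")
  }
  rows <- list()
  for (id in names(sequences)) {
    frames <- translate_six_frames(sequences[[id]], min_len = min_orf_len)
    for (i in seq_len(nrow(frames))) {
      hits <- scan_motif(frames$aa[i], leader_pattern, leader_max_mismatch)
      for (h in hits) {
        ex <- extract_core(frames$aa[i], h,
                           leader_pattern = leader_pattern,
                           recognition_pattern = recognition_pattern,
                           recognition_max_mismatch = recognition_max_mismatch,
                           core_length_window = core_length_window)
        if (ex$status != "ok") next
        fl <- classify_core(ex$core)
        rows[[length(rows) + 1]] <- data.frame(
          source_id = id, strand = frames$strand[i], frame = frames$frame[i],
          orf_aa = frames$aa[i],
          nt_start = frames$nt_start[i], nt_end = frames$nt_end[i],
          leader_start = ex$leader_span[1], leader_end = ex$leader_span[2],
          core_start = ex$core_span[1], core_end = ex$core_span[2],
          recognition_start = ex$recognition_span[1],
          recognition_end = ex$recognition_span[2],
          core = ex$core,
          disulfide_pattern = fl$disulfide_pattern, has_met = fl$has_met,
          prenylation_candidate = fl$prenylation_candidate,
          core_length = fl$length,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(source_id = character(), strand = character(),
                      frame = integer(), orf_aa = character(),
                      nt_start = integer(), nt_end = integer(),
                      leader_start = integer(), leader_end = integer(),
                      core_start = integer(), core_end = integer(),
                      recognition_start = integer(), recognition_end = integer(),
                      core = character(), disulfide_pattern = logical(),
                      has_met = logical(), prenylation_candidate = logical(),
                      core_length = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Classify a core peptide
#'
#' Structural flags read off the sequence: a double-cysteine pattern (>= 2
#' Cys) predicts an intramolecular disulfide bridge; any Met can appear as
#' the sulfoxide artifact; Ser/Thr/Tyr/Trp provide heteroatoms for
#' prenylation or geranylation.
#'
#' @param core Amino-acid string of standard residues.
#' @return A list: `disulfide_pattern`, `has_met`, `prenylation_candidate`
#'   (logicals) and `length` (integer).
#' @examples
#' classify_core("TFCDLATKQCYP")  # disulfide_pattern TRUE
#' @export
classify_core <- function(core) {
  peptide_formula(core)  # validates residues
  list(disulfide_pattern = count_residue(core, "C") >= 2,
       has_met = count_residue(core, "M") >= 1,
       prenylation_candidate = grepl("[STYW]", core),
       length = nchar(core))
}

#' Deduplicate mined cores into a clone catalog
#'
#' Collapses precursor records (one per clone) into unique core sequences
#' with clone counts, ordered by count descending then alphabetically —
#' the summary shape used for clone-library diversity, e.g. "19 unique
#' precursor cores among 122 clones".
#'
#' @param records A data.frame with at least a `core` column; a `source_id`
#'   column, if present, is aggregated. Typically the output of
#'   [mine_precursors()].
#' @return A data.frame of class `core_catalog`: `core`, `n_clones`,
#'   `source_ids` (comma-collapsed unique ids), the [classify_core()] flags
#'   and `core_length`. The summary statistics are available via
#'   [catalog_summary()].
#' @export
dedupe_cores <- function(records) {
  stopifnot(is.data.frame(records), "core" %in% names(records))
  if (nrow(records) == 0) {
    out <- data.frame(core = character(), n_clones = integer(),
                      source_ids = character(), disulfide_pattern = logical(),
                      has_met = logical(), prenylation_candidate = logical(),
                      core_length = integer(), stringsAsFactors = FALSE)
    class(out) <- c("core_catalog", "data.frame")
    return(out)
  }
  sid <- if ("source_id" %in% names(records)) records$source_id
         else rep(NA_character_, nrow(records))
  counts <- table(records$core)
  cores <- names(counts)
  ids <- vapply(cores, function(cc) {
    u <- unique(sid[records$core == cc])
    paste(u[!is.na(u)], collapse = ",")
  }, character(1))
  flags <- lapply(cores, classify_core)
  out <- data.frame(core = cores,
                    n_clones = as.integer(counts),
                    source_ids = ids,
                    disulfide_pattern = vapply(flags, `[[`, logical(1), "disulfide_pattern"),
                    has_met = vapply(flags, `[[`, logical(1), "has_met"),
                    prenylation_candidate = vapply(flags, `[[`, logical(1), "prenylation_candidate"),
                    core_length = vapply(flags, `[[`, integer(1), "length"),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_clones, out$core), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("core_catalog", "data.frame")
  out
}

#' Summary statistics of a core catalog
#'
#' @param catalog A `core_catalog` from [dedupe_cores()].
#' @return A list: `n_unique`, `total_clones`, `length_range` overall, and
#'   `length_range_disulfide` / `length_range_other` within the
#'   double-cysteine and remaining classes (NULL when a class is empty).
#' @export
catalog_summary <- function(catalog) {
  stopifnot(inherits(catalog, "core_catalog"))
  rng <- function(x) if (length(x) == 0) NULL else range(x)
  list(n_unique = nrow(catalog),
       total_clones = sum(catalog$n_clones),
       length_range = rng(catalog$core_length),
       length_range_disulfide = rng(catalog$core_length[catalog$disulfide_pattern]),
       length_range_other = rng(catalog$core_length[!catalog$disulfide_pattern]))
}
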