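# End-to-end discovery pipeline: mine precursors from DNA, catalogue cores,
# enumerate product variants, optionally assign MS1 peaks and MS2 evidence,
# and write the report tables.

#' Pipeline run configuration
#'
#' Every knob of the discovery pipeline with a documented default. Unknown
#' keys are rejected so configuration typos cannot silently change a run.
#'
#' @param ... Overrides for the defaults:
#' \describe{
#'   \item{leader_pattern}{`"KKNxxPxxxxPVxR"` — conserved leader anchor.}
#'   \item{leader_max_mismatch}{2 — substitutions tolerated in the leader.}
#'   \item{recognition_pattern}{`"FAGD"` — C-terminal recognition anchor.}
#'   \item{recognition_max_mismatch}{1.}
#'   \item{min_orf_len}{30 aa — minimum translated segment.}
#'   \item{core_length_window}{`c(5, 30)` aa.}
#'   \item{max_prenyl}{2.}
#'   \item{max_geranyl}{1.}
#'   \item{isoprenoid_cap}{2 prenyl units (geranyl counts as two).}
#'   \item{allow_disulfide_with_isoprenoid}{`TRUE`.}
#'   \item{charge}{1 — only MH+ by default.}
#'   \item{tol_mda}{20 — MS1 match tolerance, mDa (use 300 for ion traps).}
#'   \item{ms2_tol}{0.3 Da — neutral-loss tolerance.}
#'   \item{ms2_min_rel_intensity}{0.05.}
#'   \item{seed}{1 — recorded in the summary for provenance.}
#' }
#' @return A list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    leader_pattern = "KKNxxPxxxxPVxR",
    leader_max_mismatch = 2,
    recognition_pattern = "FAGD",
    recognition_max_mismatch = 1,
    min_orf_len = 30,
    core_length_window = c(5, 30),
    max_prenyl = 2,
    max_geranyl = 1,
    isoprenoid_cap = 2,
    allow_disulfide_with_isoprenoid = TRUE,
    charge = 1L,
    tol_mda = 20,
    ms2_tol = 0.3,
    ms2_min_rel_intensity = 0.05,
    seed = 1L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, overrides)
  class(cfg) <- "run_config"
  cfg
}

.config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = 10), tmp)
  unname(tools::md5sum(tmp))
}

.write_tsv <- function(df, path, digits_cols = NULL, digits = 4) {
  for (cl in intersect(digits_cols, names(df))) {
    df[[cl]] <- sprintf(paste0("%.", digits, "f"), df[[cl]])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the discovery pipeline
#'
#' Mines precursor records from the input sequences, deduplicates cores into
#' a catalog, enumerates product variants, and — when an MS1 peak list is
#' supplied — assigns peaks and annotates rank-1 matches with MS2
#' neutral-loss evidence. Writes `precursors.tsv`, `catalog.tsv`,
#' `variants.tsv`, `matches.tsv` (when peaks were given) and `summary.json`
#' under `out_dir`. Reports are deterministic and byte-stable for identical
#' inputs and configuration; nucleotide/aa spans are printed 1-based
#' inclusive; masses are printed with 4 decimals.
#'
#' @param fasta Path to a DNA FASTA file, or a named character vector of
#'   sequences.
#' @param out_dir Output directory (created if needed).
#' @param peaks Optional MS1 [peak_list] or path to a peak-list file.
#' @param ms2 Optional named list of MS2 [peak_list]s; evidence from any MS2
#'   spectrum whose precursor lies within `tol_mda` of a matched peak is
#'   attached to that match.
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory `precursors`, `catalog`,
#'   `variants`, `matches` and `summary`.
#' @export
run_pipeline <- function(fasta, out_dir, peaks = NULL, ms2 = NULL,
                         config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  seqs <- if (is.character(fasta) && length(fasta) == 1 && file.exists(fasta)) {
    read_fasta(fasta)
  } else if (is.character(fasta) && !is.null(names(fasta))) {
    fasta
  } else {
    stop("'fasta' must be a file path or a named character vector of sequences")
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (is.character(peaks)) peaks <- read_peaks(peaks)

  message(sprintf("[mine] %d input sequence(s)", length(seqs)))
  precursors <- mine_precursors(
    seqs,
    leader_pattern = config$leader_pattern,
    leader_max_mismatch = config$leader_max_mismatch,
    recognition_pattern = config$recognition_pattern,
    recognition_max_mismatch = config$recognition_max_mismatch,
    min_orf_len = config$min_orf_len,
    core_length_window = config$core_length_window)
  message(sprintf("[mine] %d precursor record(s)", nrow(precursors)))

  catalog <- dedupe_cores(precursors)
  message(sprintf("[catalog] %d unique core(s), %d clone(s)",
                  nrow(catalog), sum(catalog$n_clones)))

  variants <- if (nrow(catalog) > 0) {
    do.call(rbind, lapply(catalog$core, function(cc) {
      enumerate_variants(cc,
                         max_prenyl = config$max_prenyl,
                         max_geranyl = config$max_geranyl,
                         isoprenoid_cap = config$isoprenoid_cap,
                         allow_disulfide_with_isoprenoid =
                           config$allow_disulfide_with_isoprenoid,
                         charge = config$charge)
    }))
  } else {
    enumerate_variants("GG")[0, , drop = FALSE]
  }
  message(sprintf("[variants] %d theoretical variant(s)", nrow(variants)))

  matches <- NULL
  if (!is.null(peaks)) {
    matches <- match_peaks(variants, peaks, tol_mda = config$tol_mda)
    matches$evidence <- ""
    if (!is.null(ms2) && nrow(matches) > 0) {
      for (k in seq_len(nrow(matches))) {
        if (matches$rank[k] != 1) next
        ev <- character(0)
        for (sp in ms2) {
          if (is.null(sp$precursor_mz)) next
          if (abs(sp$precursor_mz - matches$peak_mz[k]) <= config$tol_mda / 1000) {
            ev <- union(ev, detect_neutral_losses(
              sp, tol = config$ms2_tol,
              min_rel_intensity = config$ms2_min_rel_intensity))
          }
        }
        matches$evidence[k] <- paste(sort(ev), collapse = ";")
      }
    }
    message(sprintf("[match] %d assignment(s) within %.0f mDa",
                    nrow(matches), config$tol_mda))
  }

  prec_out <- precursors
  if (nrow(prec_out) > 0) prec_out$nt_start <- prec_out$nt_start + 1  # 1-based report
  .write_tsv(prec_out, file.path(out_dir, "precursors.tsv"))
  .write_tsv(as.data.frame(catalog), file.path(out_dir, "catalog.tsv"))
  .write_tsv(variants, file.path(out_dir, "variants.tsv"), digits_cols = "mz")
  if (!is.null(matches)) {
    .write_tsv(matches, file.path(out_dir, "matches.tsv"),
               digits_cols = c("peak_mz", "theoretical_mz", "delta_mda"))
  }

  summ <- list(
    n_sequences = length(seqs),
    n_precursor_records = nrow(precursors),
    n_unique_cores = nrow(catalog),
    total_clones = if (nrow(catalog) > 0) sum(catalog$n_clones) else 0L,
    n_variants = nrow(variants),
    n_matches = if (is.null(matches)) NA else nrow(matches),
    seed = config$seed,
    config = unclass(config),
    config_hash = .config_hash(config),
    package_version = as.character(utils::packageVersion("cyanomine"))
  )
  jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 10)
  message(sprintf("[done] reports written to %s in %.1f s", out_dir,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(list(precursors = precursors, catalog = catalog,
                 variants = variants, matches = matches, summary = summ))
}
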