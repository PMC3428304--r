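# File I/O: FASTA via Biostrings; peak lists as tab-separated m/z-intensity
# columns with an optional '#'-prefixed metadata header.

#' Read a DNA FASTA file
#'
#' @param path Path to a FASTA file. Wrapped lines and mixed case are
#'   accepted; sequences are normalized to uppercase. Record order and ids
#'   are preserved.
#' @return Named character vector of uppercase DNA sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty FASTA file: ", path)
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) stop("malformed FASTA header (empty id) in ", path)
  if (any(!nzchar(seqs))) {
    stop("empty sequence for record(s): ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  stats::setNames(seqs, ids)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("'seqs' must be a fully named character vector")
  }
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a peak list from a tab-separated file
#'
#' Expected format: two tab-separated columns (m/z, intensity), optional
#' column-name header line, and optional `#`-prefixed metadata lines of the
#' form `# key=value`. MS2 files carry `# precursor_mz=<value>` (and
#' `# level=MS2`). Peaks are validated and returned sorted by m/z.
#'
#' @param path Path to the file.
#' @param level Override for the spectrum level; by default taken from the
#'   `level` metadata line, falling back to MS1.
#' @return A [peak_list].
#' @export
read_peaks <- function(path, level = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- regmatches(ml, regexec("^#\\s*([A-Za-z_]+)\\s*=\\s*(\\S+)", ml))[[1]]
    if (length(kv) == 3) meta[[kv[2]]] <- kv[3]
  }
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(body) > 0 && grepl("^[A-Za-z]", body[1])) body <- body[-1]  # header row
  if (length(body) == 0) stop("no peaks in ", path)
  parts <- strsplit(body, "\t")
  if (any(lengths(parts) < 2)) stop("expected two tab-separated columns in ", path)
  mz <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 1)))
  intensity <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2)))
  if (any(is.na(mz)) || any(is.na(intensity))) stop("non-numeric peak fields in ", path)
  lvl <- if (!is.null(level)) level else if (!is.null(meta$level)) meta$level else "MS1"
  prec <- if (!is.null(meta$precursor_mz)) as.numeric(meta$precursor_mz) else NULL
  peak_list(mz, intensity, level = lvl, precursor_mz = prec,
            source_id = basename(path))
}

#' Write a peak list to a tab-separated file
#'
#' Inverse of [read_peaks()]: metadata lines, a column header, then one
#' peak per line.
#'
#' @param pl A [peak_list].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(pl, path) {
  stopifnot(inherits(pl, "peak_list"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# level=", pl$level), con)
  if (!is.null(pl$precursor_mz)) {
    writeLines(sprintf("# precursor_mz=%.6f", pl$precursor_mz), con)
  }
  writeLines("mz\tintensity", con)
  writeLines(sprintf("%.6f\t%.6f", pl$peaks$mz, pl$peaks$intensity), con)
  invisible(path)
}
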