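# Bundled reference tables (plain-text TSVs under inst/extdata).

#' Characterized piricyclamide cores from Microcystis strains
#'
#' The core peptides of piricyclamides characterized in strain collections,
#' with their detection status (`Z` = product observed by LC-MS, `X` =
#' precursor gene only) and post-translational modifications beyond
#' macrocyclization (`G` geranyl, `P` prenyl, `SS` disulfide bridge).
#'
#' @return A data.frame: `core`, `detected`, `mods`, `strains`.
#' @export
known_cores <- function() {
  path <- system.file("extdata", "known_cores.tsv", package = "cyanomine",
                      mustWork = TRUE)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    na.strings = NULL)
}

#' Bloom-metagenome core catalog
#'
#' Unique precursor core sequences with clone counts from a cyanobacterial
#' bloom clone library (122 sequenced clones, 19 unique cores).
#'
#' @param expand If `TRUE`, return one row per clone (a record list suitable
#'   for [dedupe_cores()]); default `FALSE` returns the aggregated table.
#' @return A data.frame: `n_clones`, `core` (aggregated) or `core` repeated
#'   per clone (expanded).
#' @export
bloom_cores <- function(expand = FALSE) {
  path <- system.file("extdata", "bloom_cores.tsv", package = "cyanomine",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!expand) return(tab)
  data.frame(core = rep(tab$core, tab$n_clones), stringsAsFactors = FALSE)
}
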