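Package: cyanomine
Title: Genome Mining and Mass-Spectral Dereplication of Cyanobactin Macrocyclic Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery workflow for cyanobactins, the head-to-tail macrocyclized
    ribosomal peptides of cyanobacteria. Mines precursor genes from DNA by their
    conserved leader and C-terminal recognition motifs, extracts and catalogues
    core peptides from clone libraries, predicts the exact masses of the cyclic
    products and their prenylated, geranylated, disulfide-bridged and oxidized
    variants, verifies structures against stable-isotope (15N, 34S) label
    shifts, assigns MS1 peaks with MS2 neutral-loss diagnostics, and enumerates
    elemental formulas for unexplained mass differences. Includes a seeded
    forward simulator of precursor clone libraries and peak lists with ground
    truth, so every stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
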