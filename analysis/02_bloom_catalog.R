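#!/usr/bin/env Rscript
# Diversity of precursor cores in the bloom-metagenome clone library:
# deduplication, abundance ranking and length statistics by disulfide class.
#
# Outputs: results/bloom_catalog.tsv, results/bloom_summary.json

suppressPackageStartupMessages(library(cyanomine))
dir.create("results", showWarnings = FALSE)

catalog <- dedupe_cores(bloom_cores(expand = TRUE))
s <- catalog_summary(catalog)

write.table(as.data.frame(catalog), "results/bloom_catalog.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(s, "results/bloom_summary.json", auto_unbox = TRUE,
                     pretty = TRUE)

cat(sprintf("%d clones collapse to %d unique cores\n", s$total_clones, s$n_unique))
cat(sprintf("most abundant: %s (%d clones)\n", catalog$core[1], catalog$n_clones[1]))
cat(sprintf("double-cysteine (putative disulfide) cores: %d, lengths %s aa\n",
            sum(catalog$disulfide_pattern),
            paste(s$length_range_disulfide, collapse = " and ")))
cat(sprintf("remaining cores: %d, lengths %d-%d aa\n",
            sum(!catalog$disulfide_pattern),
            s$length_range_other[1], s$length_range_other[2]))
cat(sprintf("shared with characterized strains: %d of %d\n",
            sum(catalog$core %in% known_cores()$core), s$n_unique))
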