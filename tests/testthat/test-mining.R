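revcomp <- function(s) as.character(
  Biostrings::reverseComplement(Biostrings::DNAString(s)))

test_that("six-frame translation uses the standard code and both strands", {
  fr <- translate_six_frames("ATGGGTTAA", min_len = 1)
  expect_true(any(fr$aa == "MG" & fr$strand == "+" & fr$frame == 0))
  # reverse-complement symmetry: plus-strand frames of revcomp(s) equal
  # minus-strand frames of s
  set.seed(31)
  s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
  a <- translate_six_frames(s, min_len = 5)
  b <- translate_six_frames(revcomp(s), min_len = 5)
  expect_setequal(a$aa[a$strand == "-"], b$aa[b$strand == "+"])
  expect_setequal(a$aa[a$strand == "+"], b$aa[b$strand == "-"])
  expect_error(translate_six_frames("ATGQ"), "outside")
})

test_that("N codons translate to X and segments below the minimum are dropped", {
  fr <- translate_six_frames("ATGANTGGT", min_len = 1)
  expect_true(any(fr$aa == "MXG"))
  fr30 <- translate_six_frames(paste(rep("GGT", 20), collapse = ""), min_len = 30)
  expect_equal(nrow(fr30[fr30$strand == "+" & fr30$frame == 0, ]), 0)
})

test_that("reported nucleotide spans re-translate to the reported segment", {
  set.seed(17)
  for (i in 1:10) {
    dna <- paste(sample(c("A", "C", "G", "T"), 240, replace = TRUE), collapse = "")
    fr <- translate_six_frames(dna, min_len = 10)
    for (k in seq_len(nrow(fr))) {
      sub <- substr(dna, fr$nt_start[k] + 1, fr$nt_end[k])
      if (fr$strand[k] == "-") sub <- revcomp(sub)
      back <- as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                                 if.fuzzy.codon = "X", no.init.codon = TRUE))
      expect_identical(back, fr$aa[k])
    }
  }
})

test_that("motif scan honours wildcards, mismatch budgets and X", {
  expect_identical(scan_motif("AAKKNGGPGGGGPVGRAA", "KKNxxPxxxxPVxR"), 3L)
  mut <- "AAKANGGPGGGGPVGRAA"  # K->A at a non-wildcard position
  expect_identical(scan_motif(mut, "KKNxxPxxxxPVxR", max_mismatch = 1), 3L)
  expect_length(scan_motif(mut, "KKNxxPxxxxPVxR", max_mismatch = 0), 0)
  # X never matches, wildcards included
  expect_length(scan_motif("AAKKNGXPGGGGPVGRAA", "KKNxxPxxxxPVxR"), 0)
  expect_length(scan_motif("KKN", "KKNxxPxxxxPVxR"), 0)  # pattern longer than seq
})

test_that("motif scan equals the sliding-window oracle on random sequences", {
  set.seed(41)
  pat <- "KKNxxPxxxxPVxR"
  hits_pkg <- 0; hits_orc <- 0
  for (i in 1:1000) {
    s <- random_aa(60)
    a <- scan_motif(s, pat, 0)
    b <- oracle_scan_motif(s, pat, 0)
    expect_identical(a, b)
    hits_pkg <- hits_pkg + length(a); hits_orc <- hits_orc + length(b)
  }
  expect_identical(hits_pkg, hits_orc)
  # and with a mismatch budget on motif-bearing sequences
  for (i in 1:50) {
    s <- paste0(random_aa(10), "KKNAAPAAAAPVAR", random_aa(10))
    for (mm in 0:2) {
      expect_identical(scan_motif(s, pat, mm), oracle_scan_motif(s, pat, mm))
    }
  }
})

test_that("core extraction cuts strictly between leader end and recognition", {
  orf <- paste0("MSN", "KKNAAPAAAAPVAR", "GTHLYTITP", "FAGD", "EL")
  hit <- scan_motif(orf, "KKNxxPxxxxPVxR")
  ex <- extract_core(orf, hit[1])
  expect_identical(ex$status, "ok")
  expect_identical(ex$core, "GTHLYTITP")
  expect_identical(substr(orf, ex$core_span[1], ex$core_span[2]), ex$core)
  expect_identical(substr(orf, ex$recognition_span[1], ex$recognition_span[2]), "FAGD")
  # empty gap between leader and recognition is rejected by the length window
  orf0 <- paste0("MSN", "KKNAAPAAAAPVAR", "FAGD", "EL")
  expect_identical(extract_core(orf0, scan_motif(orf0, "KKNxxPxxxxPVxR")[1])$status,
                   "length")
  # no recognition motif downstream
  orf1 <- paste0("MSN", "KKNAAPAAAAPVAR", "GTHLYTITP", "WWWW")
  expect_identical(extract_core(orf1, scan_motif(orf1, "KKNxxPxxxxPVxR")[1],
                                recognition_max_mismatch = 0)$status,
                   "no_recognition")
})

test_that("core classification flags disulfide pattern, Met and prenylation sites", {
  fl <- classify_core("TFCDLATKQCYP")
  expect_true(fl$disulfide_pattern)
  fl2 <- classify_core("MSGVDYYNP")
  expect_true(fl2$has_met)
  expect_true(fl2$prenylation_candidate)
  fl3 <- classify_core("AAAA")
  expect_false(fl3$disulfide_pattern || fl3$has_met || fl3$prenylation_candidate)
  expect_equal(fl3$length, 4L)
})

test_that("deduplication conserves clones and orders by abundance", {
  rec <- data.frame(core = c("AAP", "GGP", "AAP", "AAP"),
                    source_id = c("s1", "s2", "s3", "s1"))
  cat <- dedupe_cores(rec)
  expect_equal(sum(cat$n_clones), nrow(rec))
  expect_identical(cat$core[1], "AAP")
  expect_identical(cat$n_clones, c(3L, 1L))
  one <- dedupe_cores(data.frame(core = "GTHLYTITP"))
  expect_equal(nrow(one), 1)
  expect_equal(one$n_clones, 1L)
  set.seed(3)
  recs <- data.frame(core = sample(c("AAP", "CCP", "WWP", "KKP"), 50, replace = TRUE))
  expect_equal(sum(dedupe_cores(recs)$n_clones), 50L)
})

test_that("the bloom catalog yields 19 unique cores totalling 122 clones", {
  cat <- dedupe_cores(bloom_cores(expand = TRUE))
  expect_equal(nrow(cat), 19)
  s <- catalog_summary(cat)
  expect_equal(s$total_clones, 122L)
  expect_equal(cat$n_clones[cat$core == "APLWDLVRWGAP"], 38L)
  expect_equal(sum(cat$disulfide_pattern), 2)
  expect_equal(sort(s$length_range_disulfide), c(10, 22))
  expect_equal(sort(s$length_range_other), c(7, 17))
})

test_that("mining is deterministic and recovers planted precursors exactly", {
  set.seed(59)
  cores <- vapply(1:20, function(i) {
    paste0(random_aa(sample(6:21, 1), setdiff(names(REFERENCE_RESIDUE_MASS), "X")), "P")
  }, character(1))
  genes <- lapply(seq_along(cores), function(i) gen_precursor_gene(cores[i], seed = 100 + i))
  seqs <- stats::setNames(vapply(genes, `[[`, character(1), "dna"),
                          sprintf("gene%02d", seq_along(genes)))
  rec <- mine_precursors(seqs, leader_max_mismatch = 0, recognition_max_mismatch = 0)
  expect_equal(nrow(rec), 20)
  expect_identical(rec$core[match(names(seqs), rec$source_id)], cores)
  # strand agreement with the generator's truth
  expect_identical(rec$strand[match(names(seqs), rec$source_id)],
                   vapply(genes, `[[`, character(1), "strand"))
  # byte-identical on re-run
  rec2 <- mine_precursors(seqs, leader_max_mismatch = 0, recognition_max_mismatch = 0)
  expect_identical(rec, rec2)
  # ORF span round-trip
  for (k in seq_len(nrow(rec))) {
    sub <- substr(seqs[[rec$source_id[k]]], rec$nt_start[k] + 1, rec$nt_end[k])
    if (rec$strand[k] == "-") sub <- revcomp(sub)
    back <- as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                               if.fuzzy.codon = "X", no.init.codon = TRUE))
    expect_identical(back, rec$orf_aa[k])
  }
})
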