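test_that("generation is a pure function of seed and config", {
  cfg <- sim_config(seed = 101, n_precursors = 6, n_clones = 15)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$fasta, b$fasta)
  expect_identical(a$truth, b$truth)
  expect_identical(a$ms1$peaks, b$ms1$peaks)
  g1 <- gen_precursor_gene("GTHLYTITP", seed = 1)
  g2 <- gen_precursor_gene("GTHLYTITP", seed = 1)
  expect_identical(g1, g2)
  expect_error(sim_config(), "mandatory")
})

test_that("planted genes are recovered by mining at zero mismatches", {
  set.seed(71)
  n_ok <- 0
  for (i in 1:100) {
    core <- paste0(random_aa(sample(6:21, 1)), "P")
    g <- gen_precursor_gene(core)
    rec <- mine_precursors(c(g1 = g$dna), leader_max_mismatch = 0,
                           recognition_max_mismatch = 0)
    if (nrow(rec) >= 1 && any(rec$core == core)) n_ok <- n_ok + 1
  }
  expect_equal(n_ok, 100)
})

test_that("clone libraries honour the configured shape and conserve clones", {
  cfg <- sim_config(seed = 7, n_precursors = 19, n_clones = 122)
  lib <- gen_clone_library(cfg)
  expect_equal(nrow(lib$truth), 19)
  expect_equal(sum(lib$truth$n_clones), 122)
  expect_equal(length(lib$fasta), 122)
  expect_true(all(nchar(lib$truth$core) >= 7 & nchar(lib$truth$core) <= 22))
  expect_true(all(substr(lib$truth$core, nchar(lib$truth$core),
                         nchar(lib$truth$core)) == "P"))
  expect_false(any(duplicated(lib$truth$core)))
  # mining the library reproduces the truth catalog exactly
  rec <- mine_precursors(lib$fasta, leader_max_mismatch = 0,
                         recognition_max_mismatch = 0)
  cat <- dedupe_cores(rec)
  expect_equal(nrow(cat), 19)
  expect_equal(sum(cat$n_clones), 122)
  got <- cat$n_clones[match(lib$truth$core, cat$core)]
  expect_identical(got, lib$truth$n_clones)
})

test_that("a zipf exponent of zero gives near-uniform clone counts", {
  for (seed in 1:50) {
    cfg <- sim_config(seed = seed, n_precursors = 10, n_clones = 200,
                      zipf_exponent = 0)
    lib <- gen_clone_library(cfg)
    p <- stats::chisq.test(lib$truth$n_clones)$p.value
    expect_gt(p, 0.01)
  }
})

test_that("peak lists plant theoretical peaks, diagnostics and bounded noise", {
  cfg <- sim_config(seed = 3, n_precursors = 8, n_clones = 20,
                    mz_error_sd_mda = 0, n_noise_peaks = 0)
  ds <- simulate_dataset(cfg)
  # zero error, zero noise: MS1 peaks sit exactly at theoretical m/z
  expect_setequal(round(ds$ms1$peaks$mz, 9), round(ds$truth$mz, 9))
  cfg2 <- sim_config(seed = 3, n_precursors = 8, n_clones = 20, n_noise_peaks = 50)
  ds2 <- simulate_dataset(cfg2)
  expect_equal(nrow(ds2$ms1$peaks), 8 + 50)
  noise <- setdiff(round(ds2$ms1$peaks$mz), round(ds2$truth$mz))
  expect_true(all(noise >= 300 & noise <= 2200))
  # every geranylated truth has both isoprenoid losses in its MS2
  ger <- ds2$truth$core_id[ds2$truth$n_geranyl > 0]
  for (id in ger) {
    ev <- detect_neutral_losses(ds2$ms2[[id]])
    expect_true(all(c("isoprenoid_loss_68", "isoprenoid_loss_136") %in% ev),
                label = id)
  }
  pren <- ds2$truth$core_id[ds2$truth$n_prenyl > 0]
  for (id in pren) {
    expect_true("isoprenoid_loss_68" %in% detect_neutral_losses(ds2$ms2[[id]]),
                label = id)
  }
})

test_that("truth coordinates point at the planted core codons", {
  set.seed(83)
  for (i in 1:10) {
    core <- paste0(random_aa(sample(6:21, 1)), "P")
    g <- gen_precursor_gene(core)
    sub <- substr(g$dna, g$core_nt_start + 1, g$core_nt_end)
    if (g$strand == "-") {
      sub <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sub)))
    }
    back <- as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                               no.init.codon = TRUE))
    expect_identical(back, core)
  }
})
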