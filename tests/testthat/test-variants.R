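test_that("variant enumeration matches the closed-form count under the caps", {
  # no Cys, no Met, caps prenyl<=2 geranyl<=1 combined<=2 units:
  # (pr, ge) in {(0,0),(1,0),(2,0),(0,1)} -> 4 variants
  v <- enumerate_variants("GTHLYTITP")
  expect_equal(nrow(v), 4)
  expect_setequal(v$variant, c("unmodified", "prenyl", "prenylx2", "geranyl"))
  expect_false(any(duplicated(v[, c("core", "variant")])))
  # a disulfide variant appears for a double-Cys core
  v2 <- enumerate_variants("TFCDLATKQCYP")
  expect_true(any(v2$n_disulfide == 1))
  expect_equal(nrow(v2), 4 * 2)  # isoprenoid states x disulfide 0..1
  # closed form with Met: x metox 0..1
  v3 <- enumerate_variants("TLGCMNGTERCLGLP")
  expect_equal(nrow(v3), 4 * 2 * 2)
  # brute-force oracle over the full grid
  oracle_n <- 0
  for (pr in 0:2) for (ge in 0:1) for (ss in 0:1) for (ox in 0:1) {
    if (pr + 2 * ge <= 2) oracle_n <- oracle_n + 1
  }
  expect_equal(nrow(v3), oracle_n)
  # disabling co-occurrence drops bridged isoprenoid variants
  v4 <- enumerate_variants("TFCDLATKQCYP", allow_disulfide_with_isoprenoid = FALSE)
  expect_false(any(v4$n_disulfide > 0 & (v4$n_prenyl + v4$n_geranyl) > 0))
})

test_that("variant m/z values are consistent with the product algebra", {
  v <- enumerate_variants("MSGVDYYNP")
  ger <- v$mz[v$variant == "geranyl"]
  un <- v$mz[v$variant == "unmodified"]
  expect_equal(ger - un, monoisotopic_mass(chem_formula("C10H16")), tolerance = 1e-9)
  # geranyl and two prenyls are isobaric at MS1
  expect_equal(v$mz[v$variant == "prenylx2"], ger, tolerance = 1e-12)
})

test_that("peak matching ranks by mass error then parsimony, deterministically", {
  v <- enumerate_variants("MSGVDYYNP")
  target <- v$mz[v$variant == "geranyl"]
  pk <- peak_list(c(target + 0.005, 500), c(100, 50))
  m <- match_peaks(v, pk, tol_mda = 20)
  best <- m[m$rank == 1 & abs(m$peak_mz - (target + 0.005)) < 1e-9, ]
  expect_equal(nrow(best), 1)
  # geranyl outranks the isobaric prenylx2 by parsimony
  expect_identical(best$variant, "geranyl")
  expect_equal(best$delta_mda, 5, tolerance = 0.01)
  # the decoy peak at 500 matches nothing
  expect_false(any(abs(m$peak_mz - 500) < 1e-9))
  # order invariance: shuffling variant rows changes nothing
  set.seed(2)
  m2 <- match_peaks(v[sample(nrow(v)), ], pk, tol_mda = 20)
  rownames(m2) <- NULL
  expect_identical(m, m2)
  # empty peak list -> empty result
  expect_equal(nrow(match_peaks(v, peak_list(numeric(0), numeric(0)), 20)), 0)
})

test_that("neutral-loss detection flags planted losses and nothing else", {
  prec <- 1120.61
  sp <- peak_list(c(prec - 68.06, prec - 136.13, 400),
                  c(800, 900, 100), level = "MS2", precursor_mz = prec)
  ev <- detect_neutral_losses(sp)
  expect_setequal(ev, c("isoprenoid_loss_68", "isoprenoid_loss_136"))
  empty <- peak_list(c(300, 500, 700), c(1, 1, 1), level = "MS2", precursor_mz = prec)
  expect_length(detect_neutral_losses(empty), 0)
  # intensity floor suppresses trace fragments
  weak <- peak_list(c(prec - 68.06, 400), c(1, 1000), level = "MS2", precursor_mz = prec)
  expect_length(detect_neutral_losses(weak, min_rel_intensity = 0.05), 0)
  expect_error(detect_neutral_losses(peak_list(400, 1)), "MS2")
})

test_that("neutral-loss detection equals a brute-force scan on random spectra", {
  losses <- neutral_loss_table()
  set.seed(13)
  for (i in 1:100) {
    prec <- stats::runif(1, 800, 1800)
    planted <- names(losses)[stats::runif(4) < 0.4]
    frag <- c(prec - losses[planted] + stats::runif(length(planted), -0.2, 0.2),
              stats::runif(5, 300, prec - 150))
    inten <- c(stats::runif(length(planted), 500, 1000), stats::runif(5, 50, 200))
    sp <- peak_list(frag, inten, level = "MS2", precursor_mz = prec)
    got <- sort(detect_neutral_losses(sp, tol = 0.3, min_rel_intensity = 0.05))
    base <- max(inten)
    want <- sort(names(losses)[vapply(losses, function(L) {
      any(abs(sp$peaks$mz - (prec - L)) <= 0.3 & sp$peaks$intensity >= 0.05 * base)
    }, logical(1))])
    expect_identical(got, want)
  }
})

test_that("label verification predicts shifts and counts atoms", {
  f <- apply_modifications(peptide_product("TLGCMNGTERCLGLP", mods = c(disulfide = 1)))
  mz <- protonated_mz(f)
  lab <- isotope_label("34S")
  # observed +4.0 Da: consistent with two labeled sulfurs even though the
  # full composition holds three (Met contributes the third)
  rep4 <- verify_labels(f, mz, mz + 4.0, lab)
  expect_equal(rep4$n_atoms_inferred, 2L)
  expect_equal(rep4$n_atoms_expected, 3L)
  expect_false(rep4$consistent)  # full labeling predicts +5.99
  rep6 <- verify_labels(f, mz, mz + 3 * lab$per_atom_delta, lab)
  expect_true(rep6$consistent)
  expect_equal(rep6$n_atoms_inferred, 3L)
  # no shift under 15N for a nitrogen-containing formula is inconsistent
  repN <- verify_labels(f, mz, mz, isotope_label("15N"))
  expect_false(repN$consistent)
  expect_equal(repN$n_atoms_inferred, 0L)
})

test_that("predicted 15N shifts agree with a per-residue oracle over random cores", {
  lab <- isotope_label("15N")
  set.seed(29)
  for (i in 1:20) {
    core <- random_aa(sample(6:20, 1))
    f <- peptide_formula(core)
    mz <- protonated_mz(f)
    shift <- oracle_nitrogen_count(core) * lab$per_atom_delta
    rep <- verify_labels(f, mz, mz + shift, lab)
    expect_true(rep$consistent, label = core)
    expect_equal(rep$n_atoms_inferred, oracle_nitrogen_count(core), label = core)
  }
})
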