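test_that("formula parsing, arithmetic and validation behave as algebra", {
  f <- chem_formula("C2H3NO")
  expect_equal(unname(f$counts[c("C", "H", "N", "O")]), c(2, 3, 1, 1))
  expect_true(chem_formula("C5H8") + chem_formula("C5H8") == chem_formula("C10H16"))
  expect_true(2 * chem_formula("C5H8") == chem_formula("C10H16"))
  expect_true(chem_formula("C10H16") - chem_formula("C5H8") == chem_formula("C5H8"))
  # commutativity / order independence
  a <- chem_formula("H2O"); b <- chem_formula("C5H8"); d <- chem_formula("NO")
  expect_true((a + b) + d == d + (b + a))
  expect_error(chem_formula("C2H3Xx1"), "malformed|unsupported")
  expect_error(chem_formula(c(C = -1)), "non-negative")
  expect_error(chem_formula("H2O") - chem_formula("H2O2"), "negative")
  expect_error(chem_formula("Fe2O3"), "unsupported")
})

test_that("isotope substitutions respect element counts and shift the mass", {
  f <- chem_formula("C3H5NOS", isotope_subs = c(`34S` = 1))
  base <- chem_formula("C3H5NOS")
  expect_equal(monoisotopic_mass(f) - monoisotopic_mass(base), 1.995796, tolerance = 1e-5)
  expect_error(chem_formula("H2O", isotope_subs = c(`15N` = 1)), "only 0")
  expect_error(chem_formula("N2", isotope_subs = c(`15N` = 3)), "only 2")
})

test_that("monoisotopic masses match reference constants", {
  expect_equal(monoisotopic_mass(chem_formula("H2O")), 18.0106, tolerance = 5e-4)
  expect_equal(monoisotopic_mass(chem_formula("C5H8")), 68.0626, tolerance = 5e-4)
  expect_equal(monoisotopic_mass(chem_formula("C10H16")), 136.1252, tolerance = 5e-4)
  expect_equal(monoisotopic_mass(chem_formula("C2H5NOS")), 91.0092, tolerance = 5e-4)
  expect_equal(monoisotopic_mass(chem_formula("CH4OS")), 63.9983, tolerance = 5e-4)
})

test_that("all 20 residue formulas match published residue masses to 1e-4 Da", {
  for (aa in names(REFERENCE_RESIDUE_MASS)) {
    expect_equal(monoisotopic_mass(residue_formula(aa)),
                 REFERENCE_RESIDUE_MASS[[aa]], tolerance = 1e-4,
                 label = paste("residue", aa))
  }
  expect_error(residue_formula("B"), "B")
  expect_error(residue_formula("X"), "X")
  expect_error(residue_formula("Z"), "Z")
})

test_that("peptide formulas: cyclic is the residue sum, linear adds water", {
  expect_true(peptide_formula("GG", "cyclic") == chem_formula("C4H6N2O2"))
  expect_true(peptide_formula("G", "linear") == chem_formula("C2H5NO2"))
  set.seed(11)
  water <- monoisotopic_mass(chem_formula("H2O"))
  for (i in 1:20) {
    core <- random_aa(sample(3:25, 1))
    expect_equal(monoisotopic_mass(peptide_formula(core, "linear")) -
                   monoisotopic_mass(peptide_formula(core, "cyclic")),
                 water, tolerance = 1e-9, label = core)
  }
  expect_error(peptide_formula(""), "non-empty")
  expect_error(peptide_formula("GXG"), "non-standard")
})

test_that("protonation arithmetic is charge-consistent", {
  f <- peptide_formula("GTHLYTITP")
  expect_equal(protonated_mz(chem_formula("H2O")), 19.0178, tolerance = 5e-4)
  for (z in 1:3) {
    expect_equal(z * protonated_mz(f, z) - z * proton_mass(),
                 monoisotopic_mass(f), tolerance = 1e-9)
  }
  expect_error(protonated_mz(f, 0), "positive integer")
  expect_error(protonated_mz(f, 1.5), "positive integer")
})

test_that("nominal mass is the integer-atomic-mass sum, not rounded monoisotopic", {
  # a ~1.5 kDa peptide ion has mass excess ~+0.7 Da: rounding would overshoot
  f <- apply_modifications(peptide_product("TLGCMNGTERCLGLP", mods = c(disulfide = 1)))
  expect_equal(nominal_mz(f), 1544)
  expect_false(round(protonated_mz(f)) == nominal_mz(f))
  expect_equal(nominal_mass(chem_formula("C5H8")), 68L)
  expect_equal(nominal_mass(chem_formula("C2H5NOS")), 91L)
})
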