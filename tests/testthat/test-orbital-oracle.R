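test_that("Hueckel spectra match the closed-form eigenvalues", {
  # ethylene: E = alpha +/- beta
  sp <- huckel_spectrum(extract_pi_system(parse_smiles("C=C")))
  expect_equal(sp$energies, c(-1, 1), tolerance = 1e-9)
  # benzene: cycle-graph eigenvalues 2cos(2*pi*k/6)
  sp <- huckel_spectrum(extract_pi_system(parse_smiles("c1ccccc1")))
  expect_equal(sp$energies, c(-2, -1, -1, 1, 1, 2), tolerance = 1e-6)
  # butadiene and hexatriene: path-graph 2cos(k*pi/(n+1))
  sp <- huckel_spectrum(extract_pi_system(parse_smiles("C=CC=C")))
  expect_equal(sp$energies, -2 * cos((1:4) * base::pi / 5), tolerance = 1e-6)
  sp <- huckel_spectrum(extract_pi_system(parse_smiles("C=CC=CC=C")))
  expect_equal(sp$energies, -2 * cos((1:6) * base::pi / 7), tolerance = 1e-6)
})

test_that("spectra satisfy the eigenvalue equation and conservation laws", {
  for (mol in fixture_molecules()) {
    ps <- tryCatch(extract_pi_system(mol), error = function(e) NULL)
    if (is.null(ps)) next
    sp <- huckel_spectrum(ps)
    # eigen residual
    res <- sp$H %*% sp$coefficients -
      sp$coefficients %*% diag(sp$energies, length(sp$energies))
    expect_lt(max(abs(res)), 1e-8, label = mol$name)
    # normalization and electron count
    expect_equal(colSums(sp$coefficients^2),
                 rep(1, length(sp$energies)), tolerance = 1e-9)
    expect_equal(sum(sp$occupations), ps$electrons)
    expect_equal(length(sp$energies), length(ps$members))
  }
})

test_that("alternant hydrocarbons obey the pairing theorem", {
  for (s in c("C=C", "C=CC=C", "C=CC=CC=C", "c1ccccc1", "C=Cc1ccccc1",
              "c1ccc2ccccc2c1")) {
    e <- huckel_spectrum(extract_pi_system(parse_smiles(s)))$energies
    expect_equal(e, -rev(e), tolerance = 1e-9, label = s)
  }
})

test_that("spectrum is invariant under atom reindexing", {
  for (mol in fixture_molecules()[c(5, 13, 19, 20, 24)]) {
    ref <- huckel_spectrum(extract_pi_system(mol))$energies
    for (s in 1:5) {
      alt <- parse_smiles(write_smiles(mol, seed = s))
      e <- huckel_spectrum(extract_pi_system(alt))$energies
      expect_equal(e, ref, tolerance = 1e-9, label = mol$name)
    }
  }
})

test_that("spectra agree with an independently assembled eigenproblem", {
  for (s in 1:25) {
    smi <- random_polyene(s)
    ps <- extract_pi_system(parse_smiles(smi))
    expect_lte(length(ps$members), 12L)
    got <- huckel_spectrum(ps)$energies
    want <- brute_force_energies(ps)
    expect_equal(got, want, tolerance = 1e-9, label = smi)
  }
})

test_that("missing parameters and open shells are reported by name", {
  ps <- extract_pi_system(parse_smiles("O=NC"))
  p <- default_huckel_params()
  p$h <- p$h[names(p$h) != "O.pi"]
  expect_error(huckel_spectrum(ps, p), "O\\.pi")
})

test_that("fragment weights are normalized orbital populations", {
  sp <- huckel_spectrum(extract_pi_system(parse_smiles("C=C")))
  expect_equal(fragment_weight(sp, 1, sp$members), 1.0)
  expect_equal(fragment_weight(sp, 2, sp$members), 1.0)
  bz <- huckel_spectrum(extract_pi_system(parse_smiles("c1ccccc1")))
  # nondegenerate orbitals spread equally: 1/6 per atom
  expect_equal(fragment_weight(bz, 1, bz$members[3]), 1 / 6, tolerance = 1e-9)
  expect_equal(fragment_weight(bz, 6, bz$members[5]), 1 / 6, tolerance = 1e-9)
  expect_error(fragment_weight(bz, 1, 99L), "outside the pi system")
  expect_error(fragment_weight(bz, 7, bz$members[1]), "out of range")
})

test_that("bond-orbital selection localizes on the fragment, not the HOMO", {
  lab <- bond_orbital_label(parse_smiles("C=C"), "C=C", threshold = 0.3)
  expect_equal(lab$hobo_energy, -1, tolerance = 1e-9)
  expect_equal(lab$lubo_energy, 1, tolerance = 1e-9)
  expect_equal(lab$hobo_weight, 1.0)
  expect_equal(lab$lubo_weight, 1.0)

  # nitrosobenzene: the global HOMO is ring-dominated; the N=O bond orbital
  # sits deeper in the occupied stack
  nb <- parse_smiles("O=Nc1ccccc1")
  ps <- extract_pi_system(nb)
  sp <- huckel_spectrum(ps)
  lab <- bond_orbital_label(nb, "N=O", threshold = 0.3)
  homo <- max(which(sp$occupations == 2L))
  expect_lt(lab$hobo_index, homo)
  expect_lt(fragment_weight(sp, homo, lab$fragment_atoms), 0.3)
  expect_gte(lab$hobo_weight, 0.3)
  expect_lt(lab$hobo_energy, lab$lubo_energy)

  # no orbital is 90% localized on one aromatic bond of benzene
  expect_error(bond_orbital_label(parse_smiles("c1ccccc1"), "cc",
                                  threshold = 0.9),
               "not localized")
  # degenerate HOMO pair of benzene: tie broken toward the lower index
  lab <- bond_orbital_label(parse_smiles("c1ccccc1"), "cc", threshold = 0.3)
  expect_equal(lab$hobo_index, 2L)
})

test_that("gap composition follows the frontier-orbital sign contract", {
  eth <- bond_orbital_label(parse_smiles("C=C"), "C=C")
  expect_equal(orbital_gap(eth, eth), 2, tolerance = 1e-9)   # self-gap 2|beta|
  cht <- bond_orbital_label(parse_smiles("C1=CC=CC=CC1"), "C=CC=CC=C")
  nb <- bond_orbital_label(parse_smiles("O=Nc1ccccc1"), "N=O")
  sty <- bond_orbital_label(parse_smiles("C=Cc1ccccc1"), "C=C")
  expect_gt(orbital_gap(cht, nb), 0)
  # nitroso enophile is predicted more reactive than styrene
  expect_lt(orbital_gap(cht, nb), orbital_gap(cht, sty))

  ev <- label_to_ev(nb)
  expect_identical(ev$unit, "eV")
  expect_error(orbital_gap(cht, ev), "unit mismatch")
  # affine map preserves ordering
  ev2 <- label_to_ev(sty)
  expect_lt(ev$lubo_energy, ev2$lubo_energy)
})

test_that("parameter files round-trip and enforce the carbon scale", {
  p <- default_huckel_params()
  expect_identical(unname(p$h[["C.pi"]]), 0)
  expect_identical(unname(p$k[["C~C.multiple"]]), 1)
  expect_match(p$checksum, "^[0-9a-f]{8}$")
  expect_error(huckel_params(h = c(C.pi = 0.1), k = p$k), "must be 0")
  expect_error(
    huckel_params(h = p$h, k = replace(p$k, "C~C.single", -1)),
    "must be 1|positive")
})
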