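test_that("SMILES parsing builds the expected heavy-atom graphs", {
  m <- parse_smiles("C=C")
  expect_equal(nrow(m$atoms), 2L)
  expect_equal(nrow(m$bonds), 1L)
  expect_equal(m$bonds$order, 2L)

  nb <- parse_smiles("O=NC1=CC=CC=C1")
  expect_equal(nrow(nb$atoms), 8L)
  expect_equal(sum(nb$atoms$aromatic), 6L)
  # N=O unit survives aromatization of the ring
  no <- nb$bonds[nb$bonds$order == 2L, ]
  expect_equal(nrow(no), 1L)
  expect_setequal(nb$atoms$element[c(no$i, no$j)], c("N", "O"))

  # implicit hydrogen inference
  expect_equal(parse_smiles("C")$atoms$h_count, 4L)
  expect_equal(parse_smiles("c1ccccc1")$atoms$h_count, rep(1L, 6L))
  expect_equal(parse_smiles("c1ccncc1")$atoms$h_count[
    parse_smiles("c1ccncc1")$atoms$element == "N"], 0L)
  pyr <- parse_smiles("c1cc[nH]c1")
  expect_equal(pyr$atoms$h_count[pyr$atoms$element == "N"], 1L)

  # charges
  cb <- parse_smiles("[O-]C(=O)c1ccccc1")
  expect_equal(sum(cb$atoms$charge), -1L)
})

test_that("parse errors name the offending position and reject fragments", {
  expect_error(parse_smiles("C=C.C"), "multi-fragment.*position 4")
  expect_error(parse_smiles("C=%C"), "position 3")
  expect_error(parse_smiles("C1CC"), "unclosed ring")
  expect_error(parse_smiles("C((C)C"), class = "error")
  expect_error(parse_smiles("[Xx]C"), "unsupported element")
  expect_error(parse_smiles(""), "non-empty")
  expect_error(parse_smiles("c1ccc1"), "aromatic")   # 4n, not aromatic
})

test_that("aromaticity perception is idempotent across kekulized spellings", {
  a <- parse_smiles("c1ccccc1")
  b <- parse_smiles("C1=CC=CC=C1")
  expect_identical(canonical_smiles(a), canonical_smiles(b))
  expect_identical(a$atoms, b$atoms)
  expect_identical(a$bonds, b$bonds)

  # kekulized pyrrole and furan normalize to the aromatic form
  expect_identical(canonical_smiles(parse_smiles("C1=CC=CN1")),
                   canonical_smiles(parse_smiles("c1cc[nH]c1")))
  expect_identical(canonical_smiles(parse_smiles("C1=CC=CO1")),
                   canonical_smiles(parse_smiles("c1ccoc1")))
  # exocyclic double bonds do not aromatize the ring
  expect_false(any(parse_smiles("O=C1C=CC(=O)C=C1")$atoms$aromatic))
})

test_that("canonical form is invariant under randomized SMILES rewriting", {
  for (mol in fixture_molecules()) {
    ref <- canonical_smiles(mol)
    for (s in 1:20) {
      rewritten <- write_smiles(mol, seed = s)
      expect_identical(canonical_smiles(parse_smiles(rewritten)), ref,
                       label = sprintf("%s via '%s'", mol$name, rewritten))
    }
  }
})

test_that("fragment matching finds exactly the expected substructures", {
  nb <- parse_smiles("O=Nc1ccccc1")
  m <- match_fragment(nb, "N=O")
  expect_length(m, 1L)
  expect_length(m[[1L]], 2L)

  # aliphatic C=C does not match aromatic bonds
  expect_length(match_fragment(parse_smiles("c1ccccc1"), "C=C"), 0L)
  # butadiene has two distinct C=C bonds
  expect_length(match_fragment(parse_smiles("C=CC=C"), "C=C"), 2L)
  # ring-membership primitive
  expect_length(match_fragment(parse_smiles("C=CC1=CCCC1"), "[CR]=[CR]"), 1L)
  # unsupported SMARTS primitives are hard errors
  expect_error(fragment_pattern("C~C"), "unsupported")
  expect_error(fragment_pattern("[C;H2]"), "unsupported")
})

test_that("fragment matching agrees with brute-force enumeration", {
  mols <- Filter(function(m) nrow(m$atoms) <= 8L, fixture_molecules())
  pats <- c("C=C", "C=O", "N=O", "cc", "C#C", "ccc", "CC=C")
  for (mol in mols) {
    for (p in pats) {
      got <- match_fragment(mol, p)
      want <- brute_force_matches(mol, p)
      expect_identical(got, want,
                       label = sprintf("%s vs '%s'", canonical_smiles(mol), p))
    }
  }
})

test_that("pi systems carry the standard electron contributions", {
  expect_pi <- function(smiles, n, e) {
    ps <- extract_pi_system(parse_smiles(smiles))
    expect_equal(length(ps$members), n, label = smiles)
    expect_equal(ps$electrons, e, label = smiles)
  }
  expect_pi("C=C", 2L, 2L)
  expect_pi("c1ccccc1", 6L, 6L)
  expect_pi("c1ccoc1", 5L, 6L)       # furan O donates a pair
  expect_pi("c1cc[nH]c1", 5L, 6L)
  expect_pi("c1ccncc1", 6L, 6L)
  expect_pi("O=NC", 2L, 2L)
  expect_pi("CC(C)=O", 2L, 2L)
  expect_pi("COC(=O)C=C", 5L, 6L)    # ester O lone pair conjugates
  expect_pi("C=Cc1ccccc1", 8L, 8L)
  expect_error(extract_pi_system(parse_smiles("CCC")), "no conjugation")
})

test_that("pi-electron count is invariant under atom reindexing", {
  for (mol in fixture_molecules()[c(4, 9, 15, 19, 22)]) {
    ref <- extract_pi_system(mol)$electrons
    for (s in 1:5) {
      alt <- parse_smiles(write_smiles(mol, seed = s))
      expect_equal(extract_pi_system(alt)$electrons, ref, label = mol$name)
    }
  }
})

test_that("smi and SDF readers round-trip structures", {
  mols <- fixture_molecules()
  expect_length(mols, 30L)
  tf <- tempfile(fileext = ".smi")
  write_smi(mols, tf)
  back <- read_smi(tf)
  expect_identical(vapply(back, canonical_smiles, ""),
                   vapply(mols, canonical_smiles, ""))

  # minimal V2000 record: nitrosobenzene, kekulized
  sdf <- c("nitrosobenzene", "  orbgap", "",
           "  8  8  0  0  0  0  0  0  0  0999 V2000",
           rep("    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0", 6),
           "    0.0000    0.0000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0",
           "    0.0000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
           "  1  2  2  0", "  2  3  1  0", "  3  4  2  0", "  4  5  1  0",
           "  5  6  2  0", "  6  1  1  0", "  1  7  1  0", "  7  8  2  0",
           "M  END", "$$$$")
  tf2 <- tempfile(fileext = ".sdf")
  writeLines(sdf, tf2)
  m <- read_sdf(tf2)[[1]]
  expect_identical(canonical_smiles(m),
                   canonical_smiles(parse_smiles("O=Nc1ccccc1")))
})
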