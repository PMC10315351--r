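test_that("builtin molecules have the expected atom counts", {
  expect_equal(numAtoms(builtinMolecule("phenol")), 13)
  expect_equal(numAtoms(builtinMolecule("paracetamol")), 20)
  expect_equal(numAtoms(builtinMolecule("n2_diphenylacetamide")), 29)
  expect_error(builtinMolecule("aspirin"), "available")
  # composition checks (formulas C6H6O, C8H9NO2)
  expect_equal(sum(atoms(builtinMolecule("phenol"))$element == "C"), 6)
  expect_equal(sum(atoms(builtinMolecule("paracetamol"))$element == "N"),
               1)
})

test_that("synthetic charges hit the integer target exactly", {
  for (t in c(0, -1, 2)) {
    g <- assignSyntheticCharges(builtinMolecule("phenol"), t, 11)
    expect_lt(abs(sum(atoms(g)$partial_charge) - t), 1e-12)
    expect_true(all(abs(atoms(g)$partial_charge) < 1.0))
  }
  g1 <- assignSyntheticCharges(builtinMolecule("phenol"), 0, 4)
  g2 <- assignSyntheticCharges(builtinMolecule("phenol"), 0, 4)
  expect_identical(atoms(g1)$partial_charge, atoms(g2)$partial_charge)
})

test_that("self-libraries cover the molecule with overlapping capped entries", {
  pa <- assignSyntheticCharges(builtinMolecule("paracetamol"), 0, 9)
  expect_error(makeSelfLibrary(builtinMolecule("paracetamol"), 3),
               "fully charged")
  # n = 1: the library is the molecule itself
  lib1 <- makeSelfLibrary(pa, 1, seed = 2)
  expect_length(libraryIds(lib1), 1)
  e1 <- libEntry(lib1, libraryIds(lib1)[1])
  expect_equal(numAtoms(e1), numAtoms(pa))
  expect_identical(atoms(e1)$partial_charge, atoms(pa)$partial_charge)
  # n = 3: cores cover all atoms, entries carry parent charges, caps
  # flagged; deterministic in the seed
  lib3 <- makeSelfLibrary(pa, 3, minOverlap = 2, k = 3, seed = 7)
  expect_length(libraryIds(lib3), 3)
  covered <- integer()
  for (id in libraryIds(lib3)) {
    e <- libEntry(lib3, id)
    real <- atoms(e)[!atoms(e)$cap, ]
    expect_identical(real$partial_charge,
                     atoms(pa)$partial_charge[match(real$id,
                                                    atoms(pa)$id)])
    covered <- union(covered, real$id)
  }
  expect_setequal(covered, atoms(pa)$id)
  lib3b <- makeSelfLibrary(pa, 3, minOverlap = 2, k = 3, seed = 7)
  expect_identical(
    lapply(libraryIds(lib3), function(id) atoms(libEntry(lib3, id))),
    lapply(libraryIds(lib3b), function(id) atoms(libEntry(lib3b, id))))
  expect_error(makeSelfLibrary(pa, 25), "infeasible")
})

test_that("self-library caps preserve boundary degrees", {
  pa <- assignSyntheticCharges(builtinMolecule("paracetamol"), 0, 9)
  lib <- makeSelfLibrary(pa, 3, minOverlap = 2, k = 3, seed = 1)
  degOf <- function(g) stats::setNames(
    fragcharge:::.degrees(g), atoms(g)$id)
  dPa <- degOf(pa)
  for (id in libraryIds(lib)) {
    e <- libEntry(lib, id)
    dE <- degOf(e)
    real <- as.character(atoms(e)$id[!atoms(e)$cap])
    expect_identical(dE[real], dPa[real])
  }
})

test_that("random molecules are connected, valence-valid and reproducible", {
  expect_equal(numAtoms(randomMolecule(1, seed = 1)), 1)
  g1 <- randomMolecule(10, seed = 5)
  g2 <- randomMolecule(10, seed = 5)
  expect_identical(atoms(g1), atoms(g2))
  expect_identical(bonds(g1), bonds(g2))
  for (s in 1:50) {
    g <- randomMolecule(sample(1:10, 1), seed = s)
    expect_true(validObject(g))
    if (numAtoms(g) > 1) {
      d <- vapply(atoms(g)$id, function(a)
        bondDistance(g, atoms(g)$id[1], a), numeric(1))
      expect_true(all(is.finite(d)))
    }
  }
  expect_error(randomMolecule(4, palette = "H", seed = 1),
               "cannot satisfy connectivity")
})
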