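test_that("SMILES parsing yields all-atom graphs with expected counts", {
  ph <- readMolecule("Oc1ccccc1", "smiles", name = "phenol")
  expect_equal(numAtoms(ph), 13)   # C6H5OH: 6 C + 6 H + 1 O
  expect_equal(numBonds(ph), 13)   # 6 ring + 6 C-H/O-H + 1 C-O
  me <- readMolecule("C", "smiles")
  expect_equal(numAtoms(me), 5)
  expect_equal(numBonds(me), 4)
  expect_error(readMolecule("", "smiles"), "parse error")
  expect_error(readMolecule("   ", "smiles"), "parse error")
})

test_that("atom ids are 0-based and deterministic across parses", {
  g1 <- readMolecule("CCO", "smiles")
  g2 <- readMolecule("CCO", "smiles")
  expect_identical(atoms(g1), atoms(g2))
  expect_identical(atoms(g1)$id, seq_len(numAtoms(g1)) - 1L)
})

test_that("bond distances satisfy the metric contract", {
  ph <- builtinMolecule("phenol")
  lm <- atoms(ph)
  o <- lm$id[lm$element == "O"]
  # para carbon: the unique ring C at distance 4 from the hydroxyl O
  d <- vapply(lm$id, function(a) bondDistance(ph, o, a), numeric(1))
  expect_equal(sum(d == 4 & lm$element == "C"), 1)
  expect_equal(bondDistance(ph, o, o), 0)
  # triangle inequality over all atom triples
  n <- numAtoms(ph)
  dm <- outer(lm$id, lm$id, Vectorize(function(a, b) bondDistance(ph, a, b)))
  for (k in seq_len(n))
    expect_true(all(dm <= dm[, k] + rep(dm[k, ], each = n) + 1e-9))
  # disconnected pair reports Inf
  two <- molecularGraph(data.frame(id = 0:1, element = c("C", "C")))
  expect_identical(bondDistance(two, 0, 1), Inf)
  expect_error(bondDistance(ph, 0, 999), "unknown atom")
})

test_that("k-balls grow monotonically up to the component", {
  ph <- builtinMolecule("phenol")
  o <- atoms(ph)$id[atoms(ph)$element == "O"]
  expect_identical(kBall(ph, o, 0), o)
  # O itself + {H(O), C1} at d1 + {C2, C6} at d2 + {H2, H6, C3, C5} at d3
  expect_length(kBall(ph, o, 3), 9)
  prev <- integer()
  for (k in 0:7) {
    cur <- kBall(ph, o, k)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
  expect_length(kBall(ph, o, 7), 13)  # diameter reached: whole component
  me <- readMolecule("C", "smiles")
  expect_length(kBall(me, 0, 1), 5)
})

test_that("atom labels report element and full connectivity", {
  ph <- builtinMolecule("phenol")
  lm <- atoms(ph)
  o <- lm$id[lm$element == "O"]
  b <- bonds(ph)
  ipso <- setdiff(c(b$a1[b$a2 == o], b$a2[b$a1 == o]),
                  lm$id[lm$element == "H"])
  expect_equal(atomLabel(ph, ipso), list(element = "C", degree = 3L))
  me <- readMolecule("C", "smiles")
  expect_equal(atomLabel(me, atoms(me)$id[atoms(me)$element == "C"]),
               list(element = "C", degree = 4L))
  h <- lm$id[lm$element == "H"][1]
  expect_equal(atomLabel(ph, h)$degree, 1L)
})

test_that("validity rules reject malformed graphs", {
  expect_error(molecularGraph(data.frame(id = c(0, 0), element = "C")),
               "unique")
  expect_error(molecularGraph(data.frame(id = 0:1, element = "C"),
                              data.frame(a1 = 0, a2 = 0, order = 1)),
               "self-bond")
  expect_error(molecularGraph(data.frame(id = 0:1, element = "C"),
                              data.frame(a1 = c(0, 1), a2 = c(1, 0),
                                         order = 1)),
               "duplicate")
  expect_error(molecularGraph(data.frame(id = 0:1, element = "C"),
                              data.frame(a1 = 0, a2 = 5, order = 1)),
               "declared atom")
  # a hydrogen with two bonds exceeds its valence
  expect_error(molecularGraph(data.frame(id = 0:2,
                                         element = c("H", "C", "C")),
                              data.frame(a1 = c(0, 0), a2 = c(1, 2),
                                         order = 1)),
               "valence")
})

test_that("SMILES and SDF routes give isomorphic labeled graphs", {
  g1 <- readMolecule("CC(=O)O", "smiles", name = "acetic")
  tf <- tempfile(fileext = ".sdf")
  writeSDF(g1, tf)
  g2 <- readMolecule(tf, "sdf", addHydrogens = FALSE)
  expect_equal(numAtoms(g2), numAtoms(g1))
  expect_length(enumerateKMCF(g1, g2, 10), 1)  # whole-graph self match
  expect_equal(fragmentSize(enumerateKMCF(g1, g2, 10)[[1]]), numAtoms(g1))
})

test_that("formal charges survive SDF round-trips", {
  am <- readMolecule("[NH4+]", "smiles")
  expect_equal(sum(atoms(am)$formal_charge), 1)
  expect_equal(netCharge(am), 1)
  tf <- tempfile(fileext = ".sdf")
  writeSDF(am, tf)
  am2 <- readMolecule(tf, "sdf", addHydrogens = FALSE)
  expect_identical(atoms(am2)$formal_charge, atoms(am)$formal_charge)
})

test_that("charge validation distinguishes finalized and draft states", {
  g <- assignSyntheticCharges(builtinMolecule("phenol"), 0, 1)
  expect_true(validateCharges(g, finalized = TRUE))
  g@atoms$partial_charge[1] <- g@atoms$partial_charge[1] + 0.3
  expect_true(validateCharges(g, finalized = FALSE))
  expect_error(validateCharges(g, finalized = TRUE), "deviates")
  g@atoms$partial_charge[1] <- NA
  expect_error(validateCharges(g), "without partial charge")
})
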