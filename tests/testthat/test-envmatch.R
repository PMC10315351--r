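test_that("compatibility is symmetric, monotone in k, and label-based at k=0", {
  ph <- builtinMolecule("phenol")
  pa <- builtinMolecule("paracetamol")
  idsP <- atoms(ph)$id; idsA <- atoms(pa)$id
  set.seed(11)
  for (i in sample(idsP, 5)) for (j in sample(idsA, 5)) {
    for (k in 0:3) {
      f <- atomsCompatible(ph, i, pa, j, k)
      expect_identical(atomsCompatible(pa, j, ph, i, k), f)
      if (f && k > 0)
        expect_true(atomsCompatible(ph, i, pa, j, k - 1))
    }
    l1 <- atomLabel(ph, i); l2 <- atomLabel(pa, j)
    expect_identical(atomsCompatible(ph, i, pa, j, 0),
                     identical(l1, l2))
  }
  expect_true(atomsCompatible(ph, 0, ph, 0, 5))
  expect_error(atomsCompatible(ph, 999, pa, 0, 3), "unknown atom")
})

test_that("every enumerated fragment passes an independent induced-isomorphism check", {
  ph <- builtinMolecule("phenol")
  pa <- builtinMolecule("paracetamol")
  bondSet <- function(g, ids) {
    b <- bonds(g)
    b <- b[b$a1 %in% ids & b$a2 %in% ids, ]
    paste(pmin(b$a1, b$a2), pmax(b$a1, b$a2))
  }
  for (mt in enumerateKMCF(ph, pa, 3)) {
    qa <- queryAtoms(mt); ra <- refAtoms(mt)
    expect_false(anyDuplicated(qa) > 0 || anyDuplicated(ra) > 0)
    # bond-preserving in both directions (induced isomorphism)
    mapR <- stats::setNames(ra, qa)
    bq <- bonds(ph); bq <- bq[bq$a1 %in% qa & bq$a2 %in% qa, ]
    mappedBonds <- paste(pmin(mapR[as.character(bq$a1)],
                              mapR[as.character(bq$a2)]),
                         pmax(mapR[as.character(bq$a1)],
                              mapR[as.character(bq$a2)]))
    expect_setequal(mappedBonds, bondSet(pa, ra))
    # connected core
    sub <- inducedSubgraph(ph, qa)
    d <- vapply(qa, function(a) bondDistance(sub, qa[1], a), numeric(1))
    expect_true(all(is.finite(d)))
    # every mapped pair k-compatible
    for (jj in seq_along(qa))
      expect_true(atomsCompatible(ph, qa[jj], pa, ra[jj], 3))
  }
})

test_that("self-matching a connected molecule returns it whole", {
  for (nm in c("phenol", "paracetamol")) {
    g <- builtinMolecule(nm)
    ms <- enumerateKMCF(g, g, 3)
    expect_equal(fragmentSize(ms[[1]]), numAtoms(g))
    expect_identical(queryAtoms(ms[[1]]), refAtoms(ms[[1]]))  # identity
  }
})

test_that("methane vs ethane at k=1 gives exactly four single-hydrogen fragments", {
  me <- readMolecule("C", "smiles")
  et <- readMolecule("CC", "smiles")
  ms <- enumerateKMCF(me, et, 1)
  expect_length(ms, 4)
  expect_true(all(vapply(ms, fragmentSize, integer(1)) == 1))
  expect_setequal(unlist(lapply(ms, queryAtoms)),
                  atoms(me)$id[atoms(me)$element == "H"])
})

test_that("no fragment is a sub-mapping of another and order is deterministic", {
  ph <- builtinMolecule("phenol")
  dp <- builtinMolecule("n2_diphenylacetamide")
  ms <- enumerateKMCF(ph, dp, 3)
  keys <- lapply(ms, function(m) paste(queryAtoms(m), refAtoms(m)))
  for (i in seq_along(ms)) for (j in seq_along(ms)) {
    if (i != j) expect_false(all(keys[[i]] %in% keys[[j]]))
  }
  sizes <- vapply(ms, fragmentSize, integer(1))
  expect_identical(sizes, sort(sizes, decreasing = TRUE))
  expect_identical(matchKey(ms), matchKey(enumerateKMCF(ph, dp, 3)))
})

test_that("enumeration agrees with the brute-force oracle on random instances", {
  set.seed(4242)
  for (s in 1:25) {
    g1 <- randomMolecule(sample(2:10, 1), seed = s)
    g2 <- randomMolecule(sample(2:10, 1), seed = s + 1000)
    for (k in 0:3)
      expect_identical(matchKey(enumerateKMCF(g1, g2, k)),
                       matchKey(bruteForceKMCF(g1, g2, k)),
                       info = sprintf("seed %d k %d", s, k))
  }
  # self matches stress the symmetry handling
  for (s in 1:8) {
    g <- randomMolecule(sample(4:10, 1), seed = s + 2000)
    for (k in 0:2)
      expect_identical(matchKey(enumerateKMCF(g, g, k)),
                       matchKey(bruteForceKMCF(g, g, k)),
                       info = sprintf("self seed %d k %d", s, k))
  }
})

test_that("the oracle refuses oversized instances", {
  g <- builtinMolecule("paracetamol")  # 20 x 29 > 400
  expect_error(bruteForceKMCF(g, builtinMolecule("n2_diphenylacetamide"), 3),
               "too large")
})

test_that("k beyond the diameter demands whole-component isomorphism", {
  g1 <- readMolecule("CCO", "smiles")
  g2 <- readMolecule("CCO", "smiles")
  ms <- enumerateKMCF(g1, g2, 50)
  expect_length(ms, 1)
  expect_equal(fragmentSize(ms[[1]]), numAtoms(g1))
  # a different molecule shares nothing at such k
  g3 <- readMolecule("CCC", "smiles")
  expect_length(enumerateKMCF(g1, g3, 50), 0)
})

test_that("library matching ranks by size and tracks per-atom coverage", {
  pa <- assignSyntheticCharges(builtinMolecule("paracetamol"), 0, 1)
  ph <- builtinMolecule("phenol")
  lib <- fragmentLibrary(list(pa), ids = "paracetamol")
  expect_error(matchLibrary(ph, new("FragmentLibrary")), "empty")
  rep <- matchLibrary(ph, lib, 3)
  sizes <- vapply(matches(rep), fragmentSize, integer(1))
  expect_identical(sizes, sort(sizes, decreasing = TRUE))
  expect_equal(sizes[1], 3)
  # fragment charge is the sum of mapped reference charges
  mt <- matches(rep)[[1]]
  refIdx <- match(refAtoms(mt), atoms(pa)$id)
  expect_equal(fragmentCharge(mt),
               sum(atoms(pa)$partial_charge[refIdx]))
  # coverage equals the union of oracle fragment cores
  oracleCov <- sort(unique(unlist(lapply(bruteForceKMCF(ph, pa, 3),
                                         queryAtoms))))
  expect_identical(rep@atomIds[coverage(rep) > 0], oracleCov)
  # self-retrieval: a library entry queried against its own library
  repSelf <- matchLibrary(pa, lib, 3)
  expect_equal(fragmentSize(matches(repSelf)[[1]]), numAtoms(pa))
  expect_true(all(coverage(repSelf) > 0))
})
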