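test_that("unmatched atoms are exactly those no fragment covers", {
  pa <- assignSyntheticCharges(builtinMolecule("paracetamol"), 0, 1)
  lib <- fragmentLibrary(list(pa), ids = "pa")
  # self-retrieval: nothing missing
  expect_length(unmatchedAtoms(matchLibrary(pa, lib, 3)), 0)
  # phenol vs {paracetamol}: complement of the oracle coverage
  ph <- builtinMolecule("phenol")
  rep <- matchLibrary(ph, lib, 3)
  oracleCov <- unique(unlist(lapply(bruteForceKMCF(ph, pa, 3),
                                    queryAtoms)))
  expect_setequal(unmatchedAtoms(rep), setdiff(atoms(ph)$id, oracleCov))
})

test_that("missing atoms group into shell-extended connected fragments", {
  ph <- builtinMolecule("phenol")
  expect_length(groupMissing(ph, integer(), 3), 0)
  # a single unmatched atom: core {a}, shell = k-ball minus the atom
  a <- atoms(ph)$id[atoms(ph)$element == "O"]
  fr <- groupMissing(ph, a, 3)
  expect_length(fr, 1)
  expect_identical(coreAtoms(fr[[1]]), a)
  expect_identical(shellAtoms(fr[[1]]), setdiff(kBall(ph, a, 3), a))
  # two adjacent unmatched atoms share one fragment core
  b <- bonds(ph)
  pairAtoms <- c(b$a1[1], b$a2[1])
  fr2 <- groupMissing(ph, pairAtoms, 3)
  expect_length(fr2, 1)
  expect_setequal(coreAtoms(fr2[[1]]), pairAtoms)
  # fragments with overlapping regions merge: every unmatched atom
  # appears in exactly one core
  un <- atoms(ph)$id[atoms(ph)$element == "C"]
  fr3 <- groupMissing(ph, un, 3)
  allCores <- unlist(lapply(fr3, coreAtoms))
  expect_identical(sort(allCores), sort(un))
  expect_false(anyDuplicated(allCores) > 0)
})

test_that("splitting respects the size limit and never cuts rings", {
  chain <- carbonChain(100)
  pieces <- splitFragment(chain, wholeMissingFragment(chain), 40)
  expect_gte(length(pieces), 3)
  for (p in pieces) {
    capped <- capFragment(chain, p)
    expect_lte(numAtoms(capped), 40)
  }
  expect_setequal(unlist(lapply(pieces, coreAtoms)), atoms(chain)$id)
  # cut bonds lie on no cycle: verify against an independent cycle basis
  ig <- igraph::graph_from_data_frame(bonds(chain)[, 1:2],
                                      directed = FALSE)
  expect_equal(igraph::ecount(ig) - igraph::vcount(ig) + 1, 0)  # a tree
  # a small fragment is returned unchanged
  small <- carbonChain(5)
  out <- splitFragment(small, wholeMissingFragment(small), 40)
  expect_length(out, 1)
  expect_identical(coreAtoms(out[[1]]), atoms(small)$id)
  # a fused polycycle with no acyclic bonds is returned whole, oversized
  na <- readMolecule("c1ccc2ccccc2c1", "smiles", addHydrogens = FALSE)
  out2 <- splitFragment(na, wholeMissingFragment(na), 5)
  expect_length(out2, 1)
  expect_setequal(coreAtoms(out2[[1]]), atoms(na)$id)
  expect_error(splitFragment(na, wholeMissingFragment(na), 3),
               "at least 5")
})

test_that("ring bonds never get cut even when rings hang off a chain", {
  # toluene-like: ring + chain; only chain bonds are cuttable
  g <- readMolecule("c1ccccc1CCCCCCCCCC", "smiles")
  frag <- wholeMissingFragment(g, 3)
  pieces <- splitFragment(g, frag, 20)
  ringIds <- kBall(g, 0, 1)
  b <- bonds(g)
  ig <- fragcharge:::.asIgraph(g)
  bridges <- igraph::bridges(ig)
  bridgeKeys <- apply(igraph::ends(ig, bridges), 1, function(e)
    paste(sort(atoms(g)$id[as.integer(e)]), collapse = "-"))
  for (i in seq_along(pieces)) for (j in seq_len(i - 1)) {
    ai <- c(coreAtoms(pieces[[i]]), shellAtoms(pieces[[i]]))
    aj <- c(coreAtoms(pieces[[j]]), shellAtoms(pieces[[j]]))
    cut <- b[(b$a1 %in% ai & b$a2 %in% aj) |
               (b$a1 %in% aj & b$a2 %in% ai), ]
    if (nrow(cut)) {
      keys <- paste(pmin(cut$a1, cut$a2), pmax(cut$a1, cut$a2),
                    sep = "-")
      expect_true(all(keys %in% bridgeKeys))
    }
  }
})

test_that("capping completes valences with neutral hydrogens", {
  # sp3 carbon with 3 open valences -> 3 hydrogens
  me0 <- readMolecule("C", "smiles")
  cId <- atoms(me0)$id[atoms(me0)$element == "C"]
  hId <- atoms(me0)$id[atoms(me0)$element == "H"][1]
  frag <- new("MissingFragment", coreAtoms = cId, shellAtoms = hId,
              k = 1L, dangling = data.frame(atom = cId, open = 3L))
  capped <- capFragment(me0, frag)
  expect_equal(numAtoms(capped), 5)          # C-H region + 3 cap H
  expect_equal(sum(atoms(capped)$cap), 3)
  expect_true(validateValence(capped))
  expect_equal(sum(atoms(capped)$formal_charge[atoms(capped)$cap]), 0)
  # a valence-complete fragment comes back unchanged, zero caps
  me <- readMolecule("C", "smiles")
  whole <- wholeMissingFragment(me)
  capped2 <- capFragment(me, whole)
  expect_equal(sum(atoms(capped2)$cap), 0)
  expect_identical(atoms(capped2)$id, atoms(me)$id)
  expect_identical(bonds(capped2), bonds(me))
  # aromatic (kekulized) ring carbon with one open valence -> one H,
  # neutral result
  bz <- readMolecule("c1ccccc1", "smiles", addHydrogens = FALSE)
  fr <- new("MissingFragment", coreAtoms = atoms(bz)$id,
            shellAtoms = integer(), k = 3L,
            dangling = data.frame(atom = integer(), open = integer()))
  capped3 <- capFragment(bz, fr)
  expect_equal(sum(atoms(capped3)$cap), 6)
  expect_true(all(atoms(capped3)$element[atoms(capped3)$cap] == "H"))
  expect_equal(sum(atoms(capped3)$formal_charge), 0)
  expect_true(validateValence(capped3))
})

test_that("capped outputs always pass valence validation", {
  set.seed(31)
  for (i in 1:10) {
    g <- randomMolecule(sample(5:12, 1), seed = i + 300)
    ids <- atoms(g)$id
    un <- sample(ids, sample(1:3, 1))
    for (frag in groupMissing(g, un, 2)) {
      capped <- capFragment(g, frag)
      tg <- fragcharge:::.valenceTargets(g)
      region <- sort(c(coreAtoms(frag), shellAtoms(frag)))
      targets <- stats::setNames(
        c(tg[match(region, ids)],
          rep(1, sum(atoms(capped)$cap))), atoms(capped)$id)
      expect_true(validateValence(capped, targets = targets))
      expect_equal(sum(atoms(capped)$formal_charge[atoms(capped)$cap]), 0)
    }
  }
})

test_that("cap selection equals exhaustive search, including rich tables", {
  rules <- readCapRules(system.file("extdata", "cap_rules_methyl.json",
                                    package = "fragcharge"))
  # up to 6 dangling atoms, each with the H-vs-methyl choice
  for (n in c(1, 3, 6)) {
    optionSets <- lapply(seq_len(n), function(i)
      fragcharge:::.capOptionsFor(rules, "C", 1))
    expect_length(optionSets[[1]], 2)
    opt <- fragcharge:::.capOptimize(optionSets)
    ex <- fragcharge:::.capExhaustive(optionSets)
    expect_identical(opt, ex)
    # hydrogen (zero heavy atoms) must win everywhere
    expect_true(all(vapply(seq_len(n), function(i)
      sum(optionSets[[i]][[opt[i]]]$element != "H") == 0, logical(1))))
  }
  # mixed open valences through the default table
  optionSets <- lapply(c(1, 2, 3, 1, 2, 3), function(v)
    fragcharge:::.capOptionsFor(defaultCapRules(), "C", v))
  expect_identical(fragcharge:::.capOptimize(optionSets),
                   fragcharge:::.capExhaustive(optionSets))
  expect_error(fragcharge:::.capOptionsFor(list(), "Xx", 1),
               "no applicable capping rule")
})
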