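# a resolved state with given values, for residual/redistribution tests
resolvedState <- function(values, target = 0) {
  g <- molecularGraph(data.frame(id = seq_along(values) - 1L,
                                 element = "C"))
  st <- newChargeState(g, target)
  for (i in seq_along(values))
    st <- resolveConflict(st, i - 1L, "manual", value = values[i])
  st
}

test_that("fragment application assigns, conflicts, and is idempotent", {
  pa <- assignSyntheticCharges(builtinMolecule("paracetamol"), 0, 1)
  lib <- fragmentLibrary(list(pa), ids = "pa")
  rep <- matchLibrary(pa, lib, 3)
  st <- newChargeState(pa, 0)
  st <- applyFragment(st, matches(rep)[[1]], lib)
  expect_true(all(atomStatus(st) == "assigned"))
  expect_equal(unname(resolvedCharges(st)), atoms(pa)$partial_charge)
  # re-applying the identical fragment adds nothing
  st2 <- applyFragment(st, matches(rep)[[1]], lib)
  expect_identical(st2@candidates, st@candidates)
  expect_false(any(atomStatus(st2) == "conflict"))
  # unknown library id errors
  badMatch <- matches(rep)[[1]]
  badMatch@libraryId <- "nope"
  expect_error(applyFragment(st, badMatch, lib), "unknown library id")
})

test_that("distinct values flag conflicts and policies resolve them", {
  g <- molecularGraph(data.frame(id = 0:1, element = c("C", "C")),
                      data.frame(a1 = 0, a2 = 1, order = 1))
  mkLib <- function(vals, id) {
    m <- g
    m@atoms$partial_charge <- vals
    fragmentLibrary(list(m), ids = id)
  }
  libA <- mkLib(c(0.10, -0.10), "A")
  libB <- mkLib(c(0.30, -0.30), "B")
  mt <- function(id) new("FragmentMatch", libraryId = id,
                         queryAtoms = c(0L, 1L), refAtoms = c(0L, 1L),
                         k = 3L, shellAtoms = integer(),
                         fragmentCharge = 0)
  st <- newChargeState(g, 0)
  st <- applyFragment(st, mt("A"), libA)
  st <- applyFragment(st, mt("B"), libB)
  expect_identical(unname(atomStatus(st)), c("conflict", "conflict"))
  expect_setequal(candidateCharges(st, 0)$value, c(0.10, 0.30))
  expect_equal(resolveConflict(st, 0, "average")@resolved[1], 0.20)
  expect_equal(resolveConflict(st, 0, "select", index = 2)@resolved[1],
               0.30)
  expect_error(resolveConflict(st, 0, "select", index = 7),
               "out of range")
  # manual targets any atom and sticks through later fragments
  st3 <- resolveConflict(newChargeState(g, 0), 1, "manual",
                         value = -0.729)
  expect_equal(st3@resolved[2], -0.729)
  st3 <- applyFragment(st3, mt("A"), libA)
  expect_equal(st3@resolved[2], -0.729)
  expect_identical(st3@status[2], "manual")
})

test_that("averaging ignores duplicates and candidate order", {
  g <- molecularGraph(data.frame(id = 0L, element = "C"))
  seqs <- list(c(0.1, 0.3, 0.1), c(0.3, 0.1, 0.3), c(0.1, 0.1, 0.3))
  outs <- vapply(seqs, function(vals) {
    st <- newChargeState(g, 0)
    for (v in vals) {
      cands <- st@candidates[[1]]
      if (!nrow(cands) || !any(abs(cands$value - v) < 1e-12))
        st@candidates[[1]] <- rbind(cands,
                                    data.frame(value = v,
                                               provenance = "x"))
    }
    st@status[1] <- "conflict"
    resolveConflict(st, 0, "average")@resolved[1]
  }, numeric(1))
  expect_true(all(abs(outs - 0.2) < 1e-12))
})

test_that("residual charge follows the sign convention sum minus target", {
  st <- resolvedState(c(0.05, 0.05), target = 0)
  expect_equal(residualCharge(st), 0.10)
  st2 <- resolvedState(c(-0.4, -0.6), target = -1)
  expect_equal(residualCharge(st2), 0.0)
  g <- molecularGraph(data.frame(id = 0:1, element = "C"))
  st3 <- newChargeState(g, 0)
  st3 <- resolveConflict(st3, 0, "manual", value = 0.1)
  expect_error(residualCharge(st3), "unresolved atom")
})

test_that("uniform redistribution restores the target and is idempotent", {
  st <- resolvedState(rep(0.01, 10), target = 0)  # sums to 0.10
  st2 <- redistributeResidual(st)
  expect_equal(st2@resolved, rep(0, 10))
  expect_identical(redistributeResidual(st2)@resolved, st2@resolved)
  # the documented division rule at realistic scale: 113 atoms, 0.445 e
  set.seed(5)
  vals <- runif(113, -0.5, 0.5)
  vals <- vals - (sum(vals) - 0.445) / 113  # make residual exactly 0.445
  st3 <- resolvedState(vals, target = 0)
  expect_equal(residualCharge(st3), 0.445)
  st4 <- redistributeResidual(st3)
  expect_equal(st4@resolved, vals - 0.445 / 113)
  expect_lt(abs(residualCharge(st4)), 1e-6)
})

test_that("redistribution conserves charge for arbitrary states", {
  set.seed(77)
  for (rep_i in 1:50) {
    n <- sample(2:60, 1)
    target <- sample(-2:2, 1)
    st <- resolvedState(runif(n, -1, 1), target = target)
    st <- redistributeResidual(st)
    expect_lt(abs(sum(st@resolved) - target), 1e-6)
    expect_lt(max(abs(redistributeResidual(st)@resolved - st@resolved)),
              1e-12)
  }
})

test_that("symmetrization averages within orbits and preserves the total", {
  me <- readMolecule("C", "smiles")
  el <- atoms(me)$element
  st <- newChargeState(me, 0)
  hVals <- c(0.1, 0.1, 0.1, 0.2); hi <- 1
  for (a in atoms(me)$id) {
    v <- if (el[match(a, atoms(me)$id)] == "C") -0.5 else {
      hv <- hVals[hi]; hi <- hi + 1; hv
    }
    st <- resolveConflict(st, a, "manual", value = v)
  }
  tot <- sum(st@resolved)
  st2 <- symmetrizeCharges(st, me)
  ch <- resolvedCharges(st2)
  expect_equal(unname(ch[el == "H"]), rep(0.125, 4))
  expect_equal(unname(ch[el == "C"]), -0.5)
  expect_equal(sum(ch), tot)
  # idempotent
  expect_equal(symmetrizeCharges(st2, me)@resolved, st2@resolved)
  # benzene: all C equal, all H equal afterwards
  bz <- readMolecule("c1ccccc1", "smiles")
  stb <- newChargeState(bz, 0)
  set.seed(2)
  for (a in atoms(bz)$id)
    stb <- resolveConflict(stb, a, "manual", value = runif(1, -0.2, 0.2))
  stb2 <- symmetrizeCharges(stb, bz)
  chb <- resolvedCharges(stb2)
  elb <- atoms(bz)$element
  expect_length(unique(round(chb[elb == "C"], 12)), 1)
  expect_length(unique(round(chb[elb == "H"], 12)), 1)
  # a molecule without symmetry is unchanged
  asym <- readMolecule("NC(=O)CO", "smiles", addHydrogens = FALSE)
  sta <- newChargeState(asym, 0)
  set.seed(3)
  for (a in atoms(asym)$id)
    sta <- resolveConflict(sta, a, "manual", value = runif(1, -0.3, 0.3))
  expect_equal(symmetrizeCharges(sta, asym)@resolved, sta@resolved)
})

test_that("equivalence classes match exhaustive expectations on benzene", {
  bz <- readMolecule("c1ccccc1", "smiles")
  cls <- equivalenceClasses(bz)
  el <- atoms(bz)$element
  expect_length(unique(cls[el == "C"]), 1)
  expect_length(unique(cls[el == "H"]), 1)
  expect_false(any(cls[el == "C"] %in% cls[el == "H"]))
})
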