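# Shared helpers for the test suite. All fixtures are generated in code.

# canonical string form of a match list, for set comparisons
matchKey <- function(ms) {
  if (!length(ms)) return(character(0))
  sort(vapply(ms, function(m)
    paste(paste(queryAtoms(m), collapse = ","),
          paste(refAtoms(m), collapse = ","), sep = "|"), character(1)))
}

# paracetamol atom ids used repeatedly: the phenolic O, its H, the ipso
# ring carbon, and the ring carbon bonded to the amide nitrogen
paracetamolLandmarks <- function(pa = builtinMolecule("paracetamol")) {
  a <- atoms(pa); b <- bonds(pa)
  nbrs <- function(x) c(b$a2[b$a1 == x], b$a1[b$a2 == x])
  deg <- function(x) length(nbrs(x))
  oH <- a$id[a$element == "O" &
               vapply(a$id, function(x)
                 a$element[match(x, a$id)] == "O" &&
                   any(a$element[match(nbrs(x), a$id)] == "H"),
                 logical(1))]
  ipso <- nbrs(oH)[a$element[match(nbrs(oH), a$id)] == "C"]
  nId <- a$id[a$element == "N"]
  nC <- nbrs(nId)[a$element[match(nbrs(nId), a$id)] == "C"]
  ringCN <- nC[vapply(nC, function(x)
    !any(a$element[match(nbrs(x), a$id)] == "O"), logical(1))]
  list(hydroxylO = oH, ipsoC = ipso, ringCamideN = ringCN)
}

# a bare n-carbon path (valence-incomplete on purpose; useful for
# splitting and capping tests)
carbonChain <- function(n) {
  molecularGraph(data.frame(id = seq_len(n) - 1L, element = "C"),
                 data.frame(a1 = seq_len(n - 1) - 1L,
                            a2 = seq_len(n - 1), order = 1),
                 name = sprintf("chain%d", n))
}

wholeMissingFragment <- function(g, k = 3L) {
  new("MissingFragment", coreAtoms = as.integer(atoms(g)$id),
      shellAtoms = integer(), k = as.integer(k),
      dangling = data.frame(atom = integer(), open = integer()))
}
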