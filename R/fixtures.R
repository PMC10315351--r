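# Built-in molecules and deterministic synthetic-data generators: every
# pipeline stage is testable without downloads or external databases.

# Structures are encoded as SMILES in source and parsed at load: no binary
# assets, bit-stable graphs. Parsed molecules are cached per session.
.BUILTIN_SMILES <- c(
  paracetamol = "CC(=O)Nc1ccc(O)cc1",
  phenol = "Oc1ccccc1",
  n2_diphenylacetamide = "O=C(Cc1ccccc1)Nc1ccccc1",
  paclitaxel = paste0(
    "CC1=C2C(C(=O)C3(C(CC4C(C3C(C(C2(C)C)(CC1OC(=O)C(C(C5=CC=CC=C5)",
    "NC(=O)C6=CC=CC=C6)O)O)OC(=O)C7=CC=CC=C7)(CO4)OC(=O)C)O)C)OC(=O)C")
)

.fixtureCache <- new.env(parent = emptyenv())

#' Built-in test molecules
#'
#' All-atom graphs of paracetamol (20 atoms), phenol (13),
#' N,2-diphenylacetamide (29) and paclitaxel (113, C47H51NO14), parsed
#' from SMILES with explicit hydrogens.
#'
#' @param name one of "paracetamol", "phenol", "n2_diphenylacetamide",
#'   "paclitaxel"
#' @return a \linkS4class{MolecularGraph}
#' @examples
#' numAtoms(builtinMolecule("paclitaxel"))  # 113
#' @export
builtinMolecule <- function(name) {
  if (!name %in% names(.BUILTIN_SMILES))
    stop("unknown fixture '", name, "'; available: ",
         paste(names(.BUILTIN_SMILES), collapse = ", "), call. = FALSE)
  hit <- .fixtureCache[[name]]
  if (!is.null(hit)) return(hit)
  g <- readMolecule(.BUILTIN_SMILES[[name]], format = "smiles",
                    name = name)
  .fixtureCache[[name]] <- g
  g
}

# run expr with a local RNG seeded at `seed`, restoring the global state
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv())
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Assign synthetic ESP-like partial charges
#'
#' Draws per-atom charges uniformly from (-0.6, 0.6) e and shifts them so
#' they sum exactly to the integer target, emulating the magnitudes of
#' ESP-fitted charges. Deterministic for a given seed.
#'
#' @param g a \linkS4class{MolecularGraph}
#' @param target integer net charge in e
#' @param seed RNG seed
#' @return the molecule with partial charges and net charge set
#' @export
assignSyntheticCharges <- function(g, target = 0, seed = 1) {
  n <- nrow(g@atoms)
  q <- .withSeed(seed, stats::runif(n, -0.6, 0.6))
  q <- q + (target - sum(q)) / n
  g@atoms$partial_charge <- q
  g@netCharge <- as.numeric(target)
  g
}

#' Build a self-library from one charged molecule
#'
#' Covers the molecule with \code{nFragments} connected, overlapping cores
#' (multi-source breadth-first partition from well-separated seed atoms,
#' then boundary extension so adjacent cores overlap by at least
#' \code{minOverlap} atoms). Each entry is a core extended by its k-shell;
#' every cut bond is replaced by one hydrogen cap carrying the removed
#' neighbor's charge (degree-preserving, so core atoms remain k-compatible
#' with their own images). Core and shell atoms carry the parent's
#' charges; the union of cores covers the molecule. Seed-deterministic.
#'
#' Reassigning the parent from its own self-library recovers every charge
#' exactly - the module's reason to exist.
#'
#' @param g a fully charged \linkS4class{MolecularGraph}
#' @param nFragments number of library entries
#' @param minOverlap minimum atom overlap between adjacent cores
#' @param k shell size used to extend each core
#' @param seed RNG seed
#' @return a \linkS4class{FragmentLibrary}
#' @export
makeSelfLibrary <- function(g, nFragments, minOverlap = 2, k = 3,
                            seed = 1) {
  if (anyNA(g@atoms$partial_charge))
    stop("molecule must be fully charged", call. = FALSE)
  stopifnot(nFragments >= 1)
  baseId <- if (nzchar(g@name)) g@name else "mol"
  if (nFragments == 1) {
    entry <- g
    entry@name <- paste0(baseId, "_frag1")
    return(fragmentLibrary(list(entry),
                           ids = paste0(baseId, "_selflib1")))
  }
  n <- nrow(g@atoms)
  if (nFragments > n)
    stop("cover infeasible: more fragments than atoms", call. = FALSE)
  d <- .distMatrix(g)
  adj <- .bfAdj(g)
  .withSeed(seed, {
    # maximin-spread seed atoms
    seeds <- sample.int(n, 1)
    while (length(seeds) < nFragments) {
      minD <- apply(d[seeds, , drop = FALSE], 2, min)
      minD[seeds] <- -1
      cand <- which(minD == max(minD))
      seeds <- c(seeds, if (length(cand) > 1) sample(cand, 1) else cand)
    }
    # multi-source BFS growth => connected cells partitioning the atoms
    cell <- rep(NA_integer_, n)
    cell[seeds] <- seq_len(nFragments)
    while (anyNA(cell)) {
      frontier <- which(!is.na(cell))
      grew <- FALSE
      for (v in sample(frontier)) {
        for (w in which(adj[v, ] & is.na(cell))) {
          cell[w] <- cell[v]
          grew <- TRUE
        }
      }
      if (!grew) stop("cover infeasible: molecule is disconnected",
                      call. = FALSE)
    }
  })
  # extend cells so adjacent cores overlap by >= minOverlap atoms
  r <- max(1, ceiling(minOverlap / 2))
  repeat {
    cores <- lapply(seq_len(nFragments), function(ci) {
      base <- which(cell == ci)
      which(colSums(d[base, , drop = FALSE] <= r) > 0)
    })
    ok <- TRUE
    for (i in seq_len(nFragments)) for (j in seq_len(i - 1)) {
      touching <- any(adj[which(cell == i), which(cell == j)])
      if (touching &&
          length(intersect(cores[[i]], cores[[j]])) < minOverlap)
        ok <- FALSE
    }
    if (ok) break
    r <- r + 1
    if (r > max(d[is.finite(d)]))
      stop("cover infeasible: overlap ", minOverlap,
           " not achievable with ", nFragments, " fragments",
           call. = FALSE)
  }
  ids <- g@atoms$id
  entries <- lapply(seq_len(nFragments), function(ci) {
    core <- ids[cores[[ci]]]
    region <- sort(unique(unlist(lapply(match(core, ids), function(i)
      ids[d[i, ] <= k]))))
    at <- g@atoms[g@atoms$id %in% region, , drop = FALSE]
    bd <- g@bonds[g@bonds$a1 %in% region & g@bonds$a2 %in% region, ,
                  drop = FALSE]
    # one hydrogen cap per cut bond, inheriting the removed neighbor's
    # charge (keeps boundary degrees identical to the parent)
    cut <- g@bonds[xor(g@bonds$a1 %in% region, g@bonds$a2 %in% region), ,
                   drop = FALSE]
    nextId <- max(region) + 1L
    for (b in seq_len(nrow(cut))) {
      inside <- if (cut$a1[b] %in% region) cut$a1[b] else cut$a2[b]
      removed <- if (cut$a1[b] %in% region) cut$a2[b] else cut$a1[b]
      at <- rbind(at, data.frame(
        id = nextId, element = "H", formal_charge = 0L,
        partial_charge =
          g@atoms$partial_charge[match(removed, g@atoms$id)],
        x = NA_real_, y = NA_real_, z = NA_real_, cap = TRUE))
      bd <- rbind(bd, data.frame(a1 = inside, a2 = nextId, order = 1))
      nextId <- nextId + 1L
    }
    molecularGraph(at, bd, name = paste0(baseId, "_frag", ci),
                   netCharge = round(sum(at$partial_charge)))
  })
  coveredCores <- sort(unique(unlist(lapply(cores, function(cc) ids[cc]))))
  if (!identical(coveredCores, sort(ids)))
    stop("cover infeasible: cores do not cover the molecule",
         call. = FALSE)
  fragmentLibrary(entries,
                  ids = paste0(baseId, "_selflib", seq_len(nFragments)))
}

#' Random valence-valid molecule generator
#'
#' Grows a random connected graph: a spanning tree attached atom by atom
#' (respecting each element's maximum valence), then a few extra
#' ring-closing bonds. Used to drive property tests against the
#' brute-force oracle. Seed-deterministic.
#'
#' @param nAtoms number of atoms
#' @param palette elements to draw from (repeats raise the weight)
#' @param seed RNG seed
#' @param cycleProb expected extra ring bonds per atom
#' @return a \linkS4class{MolecularGraph}
#' @export
randomMolecule <- function(nAtoms, palette = c("C", "C", "C", "H", "N",
                                               "O"),
                           seed = 1, cycleProb = 0.1) {
  stopifnot(nAtoms >= 1)
  .withSeed(seed, {
    el <- character(nAtoms)
    a1 <- integer(); a2 <- integer()
    deg <- integer(nAtoms)
    el[1] <- if (nAtoms == 1) sample(palette, 1) else {
      heavy <- palette[.maxValence(palette) >= 2]
      if (!length(heavy))
        stop("palette cannot satisfy connectivity for ", nAtoms,
             " atoms", call. = FALSE)
      if (length(heavy) == 1) heavy else sample(heavy, 1)
    }
    for (i in seq_len(nAtoms)[-1]) {
      hosts <- which(deg[seq_len(i - 1)] <
                       .maxValence(el[seq_len(i - 1)]))
      if (!length(hosts))
        stop("palette cannot satisfy connectivity at atom ", i,
             call. = FALSE)
      # keep enough spare valence to attach the remaining atoms
      remaining <- nAtoms - i
      pick <- NA_character_
      for (try in seq_len(50)) {
        cand <- sample(palette, 1)
        spare <- sum(.maxValence(el[seq_len(i - 1)]) -
                       deg[seq_len(i - 1)]) - 2 + .maxValence(cand)
        if (spare >= min(remaining, 1) || remaining == 0) {
          pick <- cand
          break
        }
      }
      if (is.na(pick))
        stop("palette cannot satisfy connectivity at atom ", i,
             call. = FALSE)
      el[i] <- pick
      h <- if (length(hosts) == 1) hosts else sample(hosts, 1)
      a1 <- c(a1, h); a2 <- c(a2, i)
      deg[h] <- deg[h] + 1L
      deg[i] <- deg[i] + 1L
    }
    nTry <- stats::rbinom(1, nAtoms, cycleProb)
    for (t in seq_len(nTry)) {
      free <- which(deg < .maxValence(el))
      if (length(free) < 2) break
      pr <- sample(free, 2)
      isBond <- any((a1 == pr[1] & a2 == pr[2]) |
                      (a1 == pr[2] & a2 == pr[1]))
      if (!isBond) {
        a1 <- c(a1, pr[1]); a2 <- c(a2, pr[2])
        deg[pr[1]] <- deg[pr[1]] + 1L
        deg[pr[2]] <- deg[pr[2]] + 1L
      }
    }
    molecularGraph(
      data.frame(id = seq_len(nAtoms) - 1L, element = el),
      if (length(a1)) data.frame(a1 = a1 - 1L, a2 = a2 - 1L, order = 1)
      else NULL,
      name = sprintf("random_%d_%d", nAtoms, seed))
  })
}
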