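#' Construct a MolecularGraph
#'
#' Low-level constructor. Most users will call \code{\link{readMolecule}}
#' (SMILES/SDF) or \code{\link{builtinMolecule}} instead.
#'
#' @param atoms data.frame with at least \code{id} and \code{element};
#'   missing optional columns (\code{formal_charge}, \code{partial_charge},
#'   \code{x}, \code{y}, \code{z}, \code{cap}) are filled with defaults.
#' @param bonds data.frame with columns \code{a1}, \code{a2}, \code{order}
#'   (1, 2, 3, or 4 = aromatic).
#' @param name molecule name.
#' @param netCharge target net charge in e; defaults to the sum of formal
#'   charges.
#' @return A validated \linkS4class{MolecularGraph}.
#' @examples
#' # a bare two-carbon fragment (no hydrogens)
#' g <- molecularGraph(
#'   atoms = data.frame(id = 0:1, element = "C"),
#'   bonds = data.frame(a1 = 0L, a2 = 1L, order = 1)
#' )
#' @export
molecularGraph <- function(atoms, bonds = NULL, name = "", netCharge = NULL) {
  atoms <- as.data.frame(atoms)
  if (is.null(bonds) || !nrow(as.data.frame(bonds)))
    bonds <- data.frame(a1 = integer(), a2 = integer(), order = numeric())
  bonds <- as.data.frame(bonds)
  atoms$id <- as.integer(atoms$id)
  atoms$element <- as.character(atoms$element)
  if (is.null(atoms$formal_charge)) atoms$formal_charge <- 0L
  atoms$formal_charge <- as.integer(atoms$formal_charge)
  if (is.null(atoms$partial_charge)) atoms$partial_charge <- NA_real_
  for (col in c("x", "y", "z"))
    if (is.null(atoms[[col]])) atoms[[col]] <- NA_real_
  if (is.null(atoms$cap)) atoms$cap <- FALSE
  atoms <- atoms[order(atoms$id),
                 c("id", "element", "formal_charge", "partial_charge",
                   "x", "y", "z", "cap")]
  rownames(atoms) <- NULL
  if (nrow(bonds)) {
    bonds$a1 <- as.integer(bonds$a1)
    bonds$a2 <- as.integer(bonds$a2)
    bonds$order <- as.numeric(bonds$order)
    bonds <- bonds[order(pmin(bonds$a1, bonds$a2), pmax(bonds$a1, bonds$a2)),
                   c("a1", "a2", "order")]
    rownames(bonds) <- NULL
  }
  if (is.null(netCharge)) netCharge <- sum(atoms$formal_charge)
  new("MolecularGraph", atoms = atoms, bonds = bonds, name = name,
      netCharge = as.numeric(netCharge))
}

#' @rdname fragcharge-accessors
#' @export
setMethod("atoms", "MolecularGraph", function(x) x@atoms)
#' @rdname fragcharge-accessors
#' @export
setMethod("bonds", "MolecularGraph", function(x) x@bonds)
#' @rdname fragcharge-accessors
#' @export
setMethod("molName", "MolecularGraph", function(x) x@name)
#' @rdname fragcharge-accessors
#' @export
setMethod("netCharge", "MolecularGraph", function(x) x@netCharge)
#' @rdname fragcharge-accessors
#' @export
setMethod("numAtoms", "MolecularGraph", function(x) nrow(x@atoms))
#' @rdname fragcharge-accessors
#' @export
setMethod("numBonds", "MolecularGraph", function(x) nrow(x@bonds))
#' @rdname fragcharge-accessors
#' @export
setMethod("partialCharges", "MolecularGraph", function(x) {
  stats::setNames(x@atoms$partial_charge, x@atoms$id)
})
#' @rdname fragcharge-accessors
#' @export
setMethod("partialCharges<-", "MolecularGraph", function(x, value) {
  stopifnot(length(value) == nrow(x@atoms))
  x@atoms$partial_charge <- as.numeric(value)
  x
})

setMethod("show", "MolecularGraph", function(object) {
  cat(sprintf("MolecularGraph '%s': %d atoms, %d bonds, net charge %g\n",
              object@name, nrow(object@atoms), nrow(object@bonds),
              object@netCharge))
  f <- table(object@atoms$element)
  cat("  formula:", paste0(names(f), ifelse(f > 1, f, ""), collapse = ""),
      "\n")
  if (!anyNA(object@atoms$partial_charge))
    cat(sprintf("  partial charges present (sum %.4f e)\n",
                sum(object@atoms$partial_charge)))
})

# ---- internal helpers -------------------------------------------------------

# 1-based row index for 0-based atom ids, with error on unknown ids
.atomIndex <- function(g, a) {
  i <- match(a, g@atoms$id)
  if (anyNA(i))
    stop("unknown atom id(s): ", paste(a[is.na(i)], collapse = ", "),
         call. = FALSE)
  i
}

# igraph view of the molecule (vertex order = atom order)
.asIgraph <- function(g) {
  n <- nrow(g@atoms)
  el <- cbind(match(g@bonds$a1, g@atoms$id), match(g@bonds$a2, g@atoms$id))
  ig <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(el)) ig <- igraph::add_edges(ig, t(el))
  ig
}

# full shortest-path bond-distance matrix (Inf between components)
.distMatrix <- function(g) {
  igraph::distances(.asIgraph(g))
}

# per-atom degree (all neighbors, hydrogens included)
.degrees <- function(g) {
  .degreeVector(g@atoms$id, g@bonds)
}

# per-atom label strings "element/degree"
.labels <- function(g) {
  paste0(g@atoms$element, "/", .degrees(g))
}

# numeric bond-order value for valence accounting (aromatic = 1.5)
.orderValue <- function(order) ifelse(order == 4, 1.5, order)

# per-atom sum of bond orders
.bondOrderSum <- function(g) {
  s <- numeric(nrow(g@atoms))
  if (nrow(g@bonds)) {
    ov <- .orderValue(g@bonds$order)
    i1 <- match(g@bonds$a1, g@atoms$id)
    i2 <- match(g@bonds$a2, g@atoms$id)
    for (b in seq_along(ov)) {
      s[i1[b]] <- s[i1[b]] + ov[b]
      s[i2[b]] <- s[i2[b]] + ov[b]
    }
  }
  s
}

# ---- exported graph queries -------------------------------------------------

#' Bond distance between two atoms
#'
#' Length of the shortest path between two atoms counted in bonds. Returns
#' \code{Inf} for atoms in different connected components.
#'
#' @param g a \linkS4class{MolecularGraph}
#' @param a,b atom ids
#' @return numeric bond count (0 iff \code{a == b}; \code{Inf} if
#'   unreachable).
#' @examples
#' ph <- builtinMolecule("phenol")
#' bondDistance(ph, 0, 1)
#' @export
bondDistance <- function(g, a, b) {
  i <- .atomIndex(g, c(a, b))
  d <- igraph::distances(.asIgraph(g), v = i[1], to = i[2])
  as.numeric(d[1, 1])
}

#' Atoms within k bonds of an atom
#'
#' The k-ball of an atom: all atoms at bond distance at most \code{k},
#' including the atom itself. This is the "buffer region" or shell used by
#' environment matching; with the default shell size 3, all atoms connected
#' by 3 bonds or less count as neighbors of the atom in question.
#'
#' @param g a \linkS4class{MolecularGraph}
#' @param a atom id
#' @param k shell size (bonds), non-negative
#' @return integer vector of atom ids, ascending.
#' @examples
#' ph <- builtinMolecule("phenol")
#' kBall(ph, 0, 3)
#' @export
kBall <- function(g, a, k) {
  stopifnot(k >= 0)
  i <- .atomIndex(g, a)
  d <- igraph::distances(.asIgraph(g), v = i)[1, ]
  sort(g@atoms$id[d <= k])
}

#' Atom label: element and connectivity
#'
#' The matching label of an atom: its chemical element ("type") and its
#' degree counting all bonded neighbors, hydrogens included
#' ("connectivity"). Two atoms can only be equivalent if their labels agree.
#'
#' @param g a \linkS4class{MolecularGraph}
#' @param a atom id
#' @return list with components \code{element} and \code{degree}.
#' @examples
#' atomLabel(builtinMolecule("phenol"), 0)
#' @export
atomLabel <- function(g, a) {
  i <- .atomIndex(g, a)
  list(element = g@atoms$element[i], degree = .degrees(g)[i])
}

#' Validate the partial charges of a finalized molecule
#'
#' Checks that all partial charges are present and that their sum matches
#' the net charge within a tolerance: 1e-6 e for finalized (redistributed)
#' molecules, a 0.5 e sanity bound otherwise.
#'
#' @param g a \linkS4class{MolecularGraph}
#' @param finalized logical; use the tight tolerance
#' @return invisibly TRUE; errors when the check fails.
#' @export
validateCharges <- function(g, finalized = TRUE) {
  pc <- g@atoms$partial_charge
  if (anyNA(pc))
    stop("atoms without partial charge: ",
         paste(g@atoms$id[is.na(pc)], collapse = ", "), call. = FALSE)
  tol <- if (finalized) 1e-6 else 0.5
  dev <- abs(sum(pc) - g@netCharge)
  if (dev > tol)
    stop(sprintf("charge sum deviates from net charge by %.3g e (tol %g)",
                 dev, tol), call. = FALSE)
  invisible(TRUE)
}

#' Validate valence completeness of a molecule
#'
#' Checks that every atom's bond-order sum equals its element valence
#' target (H 1, C 4, N 3, O 2, ...). Used on capped fragments, which must
#' be chemically complete.
#'
#' @param g a \linkS4class{MolecularGraph}
#' @param targets optional named numeric vector of per-atom valence targets
#'   (names = atom ids); defaults to the element table.
#' @return invisibly TRUE; errors naming offending atoms otherwise.
#' @export
validateValence <- function(g, targets = NULL) {
  s <- .bondOrderSum(g)
  if (is.null(targets)) {
    tg <- .TARGET_VALENCE[g@atoms$element]
    if (anyNA(tg))
      stop("no valence target for element(s): ",
           paste(unique(g@atoms$element[is.na(tg)]), collapse = ", "),
           call. = FALSE)
  } else {
    tg <- targets[as.character(g@atoms$id)]
  }
  bad <- abs(s - tg) > 1e-9
  if (any(bad))
    stop("incomplete valence at atom(s): ",
         paste(sprintf("%d (%s: %g of %g)", g@atoms$id[bad],
                       g@atoms$element[bad], s[bad], tg[bad]),
               collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Induced subgraph of a molecule
#'
#' @param g a \linkS4class{MolecularGraph}
#' @param ids atom ids to keep (original ids are preserved)
#' @param name name for the new molecule
#' @return a \linkS4class{MolecularGraph} on the selected atoms with all
#'   bonds among them.
#' @export
inducedSubgraph <- function(g, ids, name = g@name) {
  .atomIndex(g, ids)
  at <- g@atoms[g@atoms$id %in% ids, , drop = FALSE]
  bd <- g@bonds[g@bonds$a1 %in% ids & g@bonds$a2 %in% ids, , drop = FALSE]
  molecularGraph(at, bd, name = name,
                 netCharge = sum(at$formal_charge))
}
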