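#' @import methods
NULL

#' MolecularGraph: an all-atom molecular graph
#'
#' Atoms are nodes labeled by chemical element; covalent bonds are edges
#' labeled by bond order. Atom ids are 0-based integers, stable under
#' serialization (SDF atom-block order defines the id order). Hydrogens are
#' always explicit: matching and charge transfer operate on the all-atom
#' representation.
#'
#' @slot atoms data.frame with columns \code{id} (integer, 0-based, unique),
#'   \code{element} (character symbol), \code{formal_charge} (integer, e),
#'   \code{partial_charge} (numeric, e, may be NA), \code{x}, \code{y},
#'   \code{z} (numeric, Angstrom, may be NA) and \code{cap} (logical; TRUE
#'   for atoms added as caps, ignored by charge transfer).
#' @slot bonds data.frame with columns \code{a1}, \code{a2} (atom ids) and
#'   \code{order} (1, 2, 3, or 4 for aromatic).
#' @slot name character molecule name.
#' @slot netCharge numeric target/formal net charge in e (integer-valued).
#'
#' @examples
#' g <- readMolecule("C", format = "smiles", name = "methane")
#' numAtoms(g)
#' @export
setClass("MolecularGraph",
  representation(
    atoms = "data.frame",
    bonds = "data.frame",
    name = "character",
    netCharge = "numeric"
  ),
  prototype(
    atoms = data.frame(
      id = integer(), element = character(), formal_charge = integer(),
      partial_charge = numeric(), x = numeric(), y = numeric(),
      z = numeric(), cap = logical()
    ),
    bonds = data.frame(a1 = integer(), a2 = integer(), order = numeric()),
    name = "", netCharge = 0
  )
)

# Maximum plausible coordination number per element; a sanity bound on
# degree, deliberately permissive (e.g. N 4 covers ammonium).
.MAX_VALENCE <- c(
  H = 1, B = 4, C = 4, N = 4, O = 3, F = 1, Si = 6, P = 6, S = 6,
  Cl = 4, Br = 3, I = 3
)
.maxValence <- function(element) {
  v <- .MAX_VALENCE[element]
  v[is.na(v)] <- 8
  unname(v)
}

# Default bond-order targets used for valence completion (capping).
.TARGET_VALENCE <- c(
  H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3, S = 2,
  Cl = 1, Br = 1, I = 1
)

setValidity("MolecularGraph", function(object) {
  at <- object@atoms
  bd <- object@bonds
  msgs <- character()
  need <- c("id", "element", "formal_charge", "partial_charge", "cap")
  if (!all(need %in% names(at)))
    return(paste("atoms lacks columns:",
                 paste(setdiff(need, names(at)), collapse = ", ")))
  if (!all(c("a1", "a2", "order") %in% names(bd)))
    return("bonds lacks columns a1/a2/order")
  if (anyDuplicated(at$id)) msgs <- c(msgs, "atom ids are not unique")
  if (nrow(bd)) {
    if (any(bd$a1 == bd$a2)) msgs <- c(msgs, "self-bond present")
    key <- paste(pmin(bd$a1, bd$a2), pmax(bd$a1, bd$a2))
    if (anyDuplicated(key)) msgs <- c(msgs, "duplicate bond present")
    bad <- setdiff(c(bd$a1, bd$a2), at$id)
    if (length(bad))
      msgs <- c(msgs, paste("bond endpoint not a declared atom:",
                            paste(bad, collapse = ", ")))
    if (!all(bd$order %in% c(1, 2, 3, 4)))
      msgs <- c(msgs, "bond order must be 1, 2, 3 or 4 (aromatic)")
  }
  if (!length(msgs) && nrow(at)) {
    deg <- .degreeVector(at$id, bd)
    over <- deg > .maxValence(at$element)
    if (any(over))
      msgs <- c(msgs, paste0("degree exceeds maximum valence for atom(s) ",
                             paste(at$id[over], collapse = ", ")))
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

.degreeVector <- function(ids, bonds) {
  deg <- integer(length(ids))
  if (nrow(bonds)) {
    tab <- table(factor(c(bonds$a1, bonds$a2), levels = ids))
    deg <- as.integer(tab)
  }
  deg
}

#' FragmentLibrary: reference molecules with per-atom partial charges
#'
#' Stands in for a database of pre-parametrized compounds. Every entry is a
#' fully charged \linkS4class{MolecularGraph}; entry names are the unique
#' library ids.
#'
#' @slot entries named list of \linkS4class{MolecularGraph}, every atom
#'   carrying a partial charge; names are library ids.
#' @slot schemaVersion character version tag of the JSON serialization.
#' @export
setClass("FragmentLibrary",
  representation(entries = "list", schemaVersion = "character"),
  prototype(entries = list(), schemaVersion = "1")
)

setValidity("FragmentLibrary", function(object) {
  ids <- names(object@entries)
  if (length(object@entries)) {
    if (is.null(ids) || any(!nzchar(ids)))
      return("every entry needs a non-empty library id")
    if (anyDuplicated(ids))
      return("library ids are not unique")
    for (i in seq_along(object@entries)) {
      m <- object@entries[[i]]
      if (!is(m, "MolecularGraph"))
        return(sprintf("entry '%s' is not a MolecularGraph", ids[i]))
      if (anyNA(m@atoms$partial_charge))
        return(sprintf("entry '%s' has atoms without a partial charge",
                       ids[i]))
    }
  }
  TRUE
})

#' FragmentMatch: a k-maximal common fragment
#'
#' A bijective, bond-preserving mapping between a connected set of query
#' atoms (the core) and atoms of one library/reference molecule, in which
#' every mapped pair of atoms has isomorphic k-bond environments. The shell
#' is the set of query atoms within k bonds of the core (core excluded);
#' shell atoms constrain the match but receive no charges from it.
#'
#' @slot libraryId character id of the reference molecule ("" when matching
#'   two free molecules).
#' @slot queryAtoms integer vector of query atom ids (the core), ascending.
#' @slot refAtoms integer vector of reference atom ids aligned with
#'   \code{queryAtoms}.
#' @slot k integer shell size used for the match.
#' @slot shellAtoms integer vector of query atom ids within k bonds of the
#'   core, excluding the core.
#' @slot fragmentCharge numeric sum of reference partial charges over the
#'   mapped (non-cap) atoms; NA when the reference carries no charges.
#' @export
setClass("FragmentMatch",
  representation(
    libraryId = "character", queryAtoms = "integer", refAtoms = "integer",
    k = "integer", shellAtoms = "integer", fragmentCharge = "numeric"
  ),
  prototype(libraryId = "", queryAtoms = integer(), refAtoms = integer(),
            k = 0L, shellAtoms = integer(), fragmentCharge = NA_real_)
)

setValidity("FragmentMatch", function(object) {
  if (length(object@queryAtoms) != length(object@refAtoms))
    return("queryAtoms and refAtoms differ in length")
  if (anyDuplicated(object@queryAtoms) || anyDuplicated(object@refAtoms))
    return("mapping is not bijective")
  if (is.unsorted(object@queryAtoms))
    return("queryAtoms must be ascending")
  TRUE
})

#' MatchReport: library-wide match result for one query molecule
#'
#' @slot matches list of \linkS4class{FragmentMatch}, ranked by size
#'   (descending) with deterministic tie-breaks (library id, then query atom
#'   ids).
#' @slot coverage integer vector, one entry per query atom (in atom-id
#'   order): number of fragments whose core covers the atom via a non-cap
#'   reference atom. Zero marks a "missing" atom.
#' @slot k integer shell size.
#' @slot queryName character.
#' @export
setClass("MatchReport",
  representation(matches = "list", coverage = "integer",
                 atomIds = "integer", k = "integer",
                 queryName = "character"),
  prototype(matches = list(), coverage = integer(), atomIds = integer(),
            k = 3L, queryName = "")
)

#' ChargeState: per-atom charge candidates and resolution status
#'
#' Collects candidate charges transferred from fragments, tracks conflicts
#' (two or more distinct candidate values), resolved values, and the
#' residual relative to the target net charge.
#'
#' @slot nAtoms integer number of query atoms.
#' @slot atomIds integer query atom ids (ascending).
#' @slot candidates list (one element per atom) of data.frames with columns
#'   \code{value} (numeric, e) and \code{provenance} (character,
#'   "libraryId:refAtom" or "manual").
#' @slot resolved numeric per-atom resolved charge (NA while unresolved).
#' @slot status character per-atom status: unassigned, assigned, conflict,
#'   or manual.
#' @slot targetCharge numeric target net charge in e.
#' @export
setClass("ChargeState",
  representation(
    nAtoms = "integer", atomIds = "integer", candidates = "list",
    resolved = "numeric", status = "character", targetCharge = "numeric"
  )
)

setValidity("ChargeState", function(object) {
  n <- object@nAtoms
  if (length(object@atomIds) != n) return("atomIds length != nAtoms")
  if (length(object@candidates) != n) return("candidates length != nAtoms")
  if (length(object@resolved) != n) return("resolved length != nAtoms")
  if (length(object@status) != n) return("status length != nAtoms")
  if (!all(object@status %in% c("unassigned", "assigned", "conflict",
                                "manual")))
    return("invalid status value")
  TRUE
})

#' MissingFragment: a connected unmatched region plus its shell
#'
#' @slot coreAtoms integer unmatched query atom ids.
#' @slot shellAtoms integer atoms within k bonds of the core (core
#'   excluded).
#' @slot k integer shell size used to build the shell.
#' @slot dangling data.frame with columns \code{atom} (id) and \code{open}
#'   (integer open valence: bond-order units missing relative to the atom's
#'   valence target).
#' @export
setClass("MissingFragment",
  representation(coreAtoms = "integer", shellAtoms = "integer",
                 k = "integer", dangling = "data.frame"),
  prototype(coreAtoms = integer(), shellAtoms = integer(), k = 3L,
            dangling = data.frame(atom = integer(), open = integer()))
)
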