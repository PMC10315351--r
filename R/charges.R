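# Charge transfer, conflict resolution, residual correction and
# symmetrization.

#' Create an empty charge state for a query molecule
#'
#' @param g query \linkS4class{MolecularGraph}
#' @param targetCharge target net charge in e (default: the molecule's net
#'   charge)
#' @return a \linkS4class{ChargeState} with every atom unassigned
#' @export
newChargeState <- function(g, targetCharge = netCharge(g)) {
  n <- nrow(g@atoms)
  new("ChargeState",
      nAtoms = n, atomIds = as.integer(g@atoms$id),
      candidates = rep(list(data.frame(value = numeric(),
                                       provenance = character())), n),
      resolved = rep(NA_real_, n),
      status = rep("unassigned", n),
      targetCharge = as.numeric(targetCharge))
}

#' @rdname fragcharge-accessors
#' @export
setMethod("resolvedCharges", "ChargeState",
          function(x) stats::setNames(x@resolved, x@atomIds))
#' @rdname fragcharge-accessors
#' @export
setMethod("atomStatus", "ChargeState",
          function(x) stats::setNames(x@status, x@atomIds))
#' @rdname fragcharge-accessors
#' @export
setMethod("targetCharge", "ChargeState", function(x) x@targetCharge)
#' @rdname fragcharge-accessors
#' @export
setMethod("numAtoms", "ChargeState", function(x) x@nAtoms)

#' Candidate charges of one atom
#' @param x a \linkS4class{ChargeState}
#' @param atom atom id
#' @return data.frame with columns value, provenance
#' @export
candidateCharges <- function(x, atom) {
  i <- match(atom, x@atomIds)
  if (is.na(i)) stop("unknown atom id ", atom, call. = FALSE)
  x@candidates[[i]]
}

setMethod("show", "ChargeState", function(object) {
  tab <- table(factor(object@status,
                      levels = c("unassigned", "assigned", "conflict",
                                 "manual")))
  cat(sprintf("ChargeState: %d atoms, target %g e\n", object@nAtoms,
              object@targetCharge))
  cat(sprintf("  unassigned %d | assigned %d | conflict %d | manual %d\n",
              tab[1], tab[2], tab[3], tab[4]))
  if (!anyNA(object@resolved))
    cat(sprintf("  residual %.6f e\n",
                sum(object@resolved) - object@targetCharge))
})

#' Transfer charges from a matched fragment to the query
#'
#' For every mapped pair the reference atom's partial charge is appended
#' as a candidate for the query atom. Reference cap atoms are skipped
#' (their charges are bookkeeping, not transferable values). Duplicate
#' candidate values (within 1e-12 e) collapse on entry, so re-applying the
#' same fragment changes nothing; an atom that accumulates two or more
#' distinct values becomes a conflict.
#'
#' @param state a \linkS4class{ChargeState}
#' @param match a \linkS4class{FragmentMatch} with a library id
#' @param lib the \linkS4class{FragmentLibrary} the match refers to
#' @return the updated \linkS4class{ChargeState}
#' @export
applyFragment <- function(state, match, lib) {
  entry <- libEntry(lib, libraryId(match))  # errors on unknown id
  refIdx <- match(match@refAtoms, entry@atoms$id)
  for (jj in seq_along(match@queryAtoms)) {
    ri <- refIdx[jj]
    if (entry@atoms$cap[ri]) next
    val <- entry@atoms$partial_charge[ri]
    prov <- paste0(libraryId(match), ":", match@refAtoms[jj])
    i <- match(match@queryAtoms[jj], state@atomIds)
    cands <- state@candidates[[i]]
    if (!nrow(cands) || !any(abs(cands$value - val) < 1e-12)) {
      cands <- rbind(cands, data.frame(value = val, provenance = prov))
      state@candidates[[i]] <- cands
    }
    if (state@status[i] == "manual") next
    if (nrow(cands) >= 2) {
      state@status[i] <- "conflict"
      state@resolved[i] <- NA_real_
    } else {
      state@status[i] <- "assigned"
      state@resolved[i] <- cands$value[1]
    }
  }
  state
}

#' Resolve the charge of an atom
#'
#' Policies follow the interactive options: select one of the alternative
#' partial charges, average the distinct values, or manually provide a new
#' value (manual may target any atom and always sticks).
#'
#' @param state a \linkS4class{ChargeState}
#' @param atom atom id
#' @param policy "select", "average" or "manual"
#' @param index candidate row (1-based) for \code{policy = "select"}
#' @param value charge in e for \code{policy = "manual"}
#' @return the updated \linkS4class{ChargeState}
#' @export
resolveConflict <- function(state, atom,
                            policy = c("select", "average", "manual"),
                            index = NULL, value = NULL) {
  policy <- match.arg(policy)
  i <- match(atom, state@atomIds)
  if (is.na(i)) stop("unknown atom id ", atom, call. = FALSE)
  cands <- state@candidates[[i]]
  if (policy == "manual") {
    if (is.null(value)) stop("manual policy needs a value", call. = FALSE)
    state@candidates[[i]] <-
      rbind(cands, data.frame(value = value, provenance = "manual"))
    state@resolved[i] <- as.numeric(value)
    state@status[i] <- "manual"
    return(state)
  }
  if (!nrow(cands))
    stop("atom ", atom, " has no candidate charges", call. = FALSE)
  if (policy == "select") {
    if (is.null(index) || index < 1 || index > nrow(cands))
      stop("select index out of range for atom ", atom, " (",
           nrow(cands), " candidates)", call. = FALSE)
    state@resolved[i] <- cands$value[index]
  } else {
    state@resolved[i] <- mean(cands$value)
  }
  state@status[i] <- "assigned"
  state
}

#' Resolve every conflicted atom with one policy
#'
#' Batch counterpart of \code{\link{resolveConflict}}: averaging (the
#' default) or selecting the first-transferred candidate.
#'
#' @param state a \linkS4class{ChargeState}
#' @param policy "average" or "select"
#' @return the updated \linkS4class{ChargeState}
#' @export
resolveAllConflicts <- function(state, policy = c("average", "select")) {
  policy <- match.arg(policy)
  for (a in state@atomIds[state@status == "conflict"]) {
    state <- if (policy == "average") {
      resolveConflict(state, a, "average")
    } else {
      resolveConflict(state, a, "select", index = 1)
    }
  }
  state
}

#' Residual charge of a fully resolved state
#'
#' The difference between the sum of assigned charges and the target net
#' charge (positive = excess positive charge), so subtracting
#' residual/N from each atom restores the target exactly.
#'
#' @param state a \linkS4class{ChargeState} with every atom resolved
#' @return numeric residual in e
#' @export
residualCharge <- function(state) {
  un <- state@atomIds[is.na(state@resolved)]
  if (length(un))
    stop("unresolved atom(s): ", paste(un, collapse = ", "),
         call. = FALSE)
  sum(state@resolved) - state@targetCharge
}

#' Distribute the residual charge uniformly
#'
#' Subtracts residual/N from every atom so the sum of charges equals the
#' target net charge (within 1e-6 e); applying it again is a no-op.
#'
#' @param state a fully resolved \linkS4class{ChargeState}
#' @return the corrected \linkS4class{ChargeState}
#' @export
redistributeResidual <- function(state) {
  if (state@nAtoms == 0) stop("state has no atoms", call. = FALSE)
  res <- residualCharge(state)
  state@resolved <- state@resolved - res / state@nAtoms
  state
}

#' Topological equivalence classes of atoms
#'
#' Orbits of the automorphism group of the element-labeled molecular
#' graph, computed by iterated neighborhood-label refinement run to a
#' fixed point and then refined exactly with the automorphism group
#' (BLISS). Atoms in one class are topologically interchangeable (e.g.,
#' the three hydrogens of a methyl group, or benzene's six carbons).
#'
#' @param g a \linkS4class{MolecularGraph}
#' @return integer vector of class indices, one per atom (in id order)
#' @export
equivalenceClasses <- function(g) {
  n <- nrow(g@atoms)
  if (n == 0) return(integer())
  adj <- .bfAdj(g)
  cls <- match(g@atoms$element, unique(g@atoms$element))
  repeat {
    sigs <- vapply(seq_len(n), function(i)
      paste(cls[i], paste(sort(cls[adj[i, ]]), collapse = ","),
            sep = "|"), character(1))
    newCls <- match(sigs, unique(sigs))
    if (identical(newCls, cls)) break
    cls <- newCls
  }
  # exact refinement: orbits of the automorphism group within WL classes
  gens <- tryCatch(
    igraph::automorphism_group(.asIgraph(g), colors = cls),
    error = function(e) NULL)
  if (!is.null(gens)) {
    parent <- seq_len(n)
    findRoot <- function(x) {
      while (parent[x] != x) {
        parent[x] <<- parent[parent[x]]
        x <- parent[x]
      }
      x
    }
    for (p in gens) {
      perm <- as.integer(p)
      for (v in seq_len(n)) {
        a <- findRoot(v); b <- findRoot(perm[v])
        if (a != b) parent[a] <- b
      }
    }
    roots <- vapply(seq_len(n), findRoot, integer(1))
    cls <- match(roots, unique(roots))
  }
  cls
}

#' Symmetrize resolved charges over topological equivalence classes
#'
#' Atoms in the same equivalence class (see
#' \code{\link{equivalenceClasses}}) receive the class mean; the total
#' charge is unchanged.
#'
#' @param state a fully resolved \linkS4class{ChargeState}
#' @param g the query \linkS4class{MolecularGraph}
#' @return the symmetrized \linkS4class{ChargeState}
#' @export
symmetrizeCharges <- function(state, g) {
  un <- state@atomIds[is.na(state@resolved)]
  if (length(un))
    stop("unresolved atom(s): ", paste(un, collapse = ", "),
         call. = FALSE)
  cls <- equivalenceClasses(g)
  means <- tapply(state@resolved, cls, mean)
  state@resolved <- as.numeric(means[as.character(cls)])
  state
}
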