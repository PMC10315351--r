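# Batch workflow: matching, greedy fragment selection, charge assignment,
# residual correction, multi-start consistency runs, and the command-level
# functions behind the shell interface.

# fragments covering a given query atom through a non-cap reference atom
.fragmentsCovering <- function(report, lib, atom) {
  hits <- integer()
  for (i in seq_along(report@matches)) {
    mt <- report@matches[[i]]
    jj <- match(atom, mt@queryAtoms)
    if (is.na(jj)) next
    entry <- lib@entries[[mt@libraryId]]
    if (entry@atoms$cap[match(mt@refAtoms[jj], entry@atoms$id)]) next
    hits <- c(hits, i)
  }
  hits
}

#' Greedy automated charge assignment
#'
#' Scriptable replacement for interactive fragment selection, following
#' the multi-start protocol: pick a (seeded) starting atom, apply the
#' largest fragment covering it, then repeatedly pick another
#' unparametrized atom and apply the largest covering fragment that
#' overlaps no previously assigned atom, falling back to the largest
#' covering fragment when every candidate overlaps. Conflicts are then
#' resolved by the configured policy, the residual charge is
#' redistributed uniformly, and charges are optionally symmetrized.
#'
#' @param query \linkS4class{MolecularGraph}
#' @param lib \linkS4class{FragmentLibrary}
#' @param k shell size (default 3)
#' @param policy conflict policy, "average" (default) or "select" (first
#'   transferred value wins)
#' @param targetCharge target net charge (default: the query's)
#' @param seed RNG seed controlling the start-atom choices
#' @param symmetrize logical; average charges over topological
#'   equivalence classes after redistribution
#' @param manualCharges optional named numeric vector (names = atom ids)
#'   for atoms the library cannot cover
#' @param report optional precomputed \linkS4class{MatchReport} (saves
#'   recomputation across seeds)
#' @return list with elements \code{state} (\linkS4class{ChargeState}),
#'   \code{charges} (named numeric), \code{log} (data.frame of fragment
#'   decisions), \code{report}, \code{residualBefore},
#'   \code{residualAfter}.
#' @export
greedyAssign <- function(query, lib, k = 3,
                         policy = c("average", "select"),
                         targetCharge = netCharge(query), seed = 1,
                         symmetrize = FALSE, manualCharges = NULL,
                         report = NULL) {
  policy <- match.arg(policy)
  if (is.null(report)) report <- matchLibrary(query, lib, k)
  state <- newChargeState(query, targetCharge)
  covered <- report@atomIds[report@coverage > 0]
  uncovered <- setdiff(report@atomIds, covered)
  manualIds <- if (is.null(manualCharges)) integer() else
    as.integer(names(manualCharges))
  bare <- setdiff(uncovered, manualIds)
  if (length(bare))
    stop("no fragment covers atom(s) ", paste(bare, collapse = ", "),
         " and no manual charge was provided", call. = FALSE)
  sizes <- vapply(report@matches, function(m) length(m@queryAtoms),
                  integer(1))
  logRows <- list()
  .withSeed(seed, {
    repeat {
      todo <- intersect(covered,
                        state@atomIds[state@status == "unassigned"])
      if (!length(todo)) break
      start <- if (length(todo) == 1) todo else sample(todo, 1)
      cand <- .fragmentsCovering(report, lib, start)
      assigned <- state@atomIds[state@status != "unassigned"]
      # largest fragment wins (overlap extent is the quality signal);
      # among the largest, prefer one that overlaps no assigned atom
      top <- cand[sizes[cand] == max(sizes[cand])]
      overlapFree <- top[vapply(top, function(i)
        !any(report@matches[[i]]@queryAtoms %in% assigned), logical(1))]
      pick <- if (length(overlapFree)) overlapFree[1] else top[1]
      mt <- report@matches[[pick]]
      state <- applyFragment(state, mt, lib)
      logRows[[length(logRows) + 1]] <- data.frame(
        start_atom = start, library_id = mt@libraryId,
        size = length(mt@queryAtoms),
        fragment_charge = mt@fragmentCharge,
        overlap_free = length(overlapFree) > 0)
    }
  })
  for (a in manualIds)
    state <- resolveConflict(state, a, "manual",
                             value = manualCharges[[as.character(a)]])
  state <- resolveAllConflicts(state, policy)
  residBefore <- residualCharge(state)
  state <- redistributeResidual(state)
  if (symmetrize) state <- symmetrizeCharges(state, query)
  residAfter <- residualCharge(state)
  list(state = state, charges = resolvedCharges(state),
       log = if (length(logRows)) do.call(rbind, logRows) else
         data.frame(),
       report = report, residualBefore = residBefore,
       residualAfter = residAfter)
}

#' Multi-start consistency runs
#'
#' Runs \code{\link{greedyAssign}} once per seed (sharing one match
#' report) and summarizes the spread of the resulting charge sets: the
#' per-atom standard deviation across starts measures how consistent the
#' assignment is.
#'
#' @inheritParams greedyAssign
#' @param seeds integer vector of seeds, one run each (default 1:5)
#' @return list with \code{charges} (atoms x runs matrix), \code{sd}
#'   (named per-atom standard deviation), \code{residualsBefore},
#'   \code{results} (per-seed results)
#' @export
multiStartAssign <- function(query, lib, k = 3, seeds = 1:5,
                             policy = c("average", "select"),
                             targetCharge = netCharge(query),
                             symmetrize = FALSE) {
  policy <- match.arg(policy)
  report <- matchLibrary(query, lib, k)
  runs <- lapply(seeds, function(s)
    greedyAssign(query, lib, k, policy, targetCharge, seed = s,
                 symmetrize = symmetrize, report = report))
  mat <- vapply(runs, function(rn) unname(rn$charges),
                numeric(nrow(query@atoms)))
  rownames(mat) <- query@atoms$id
  colnames(mat) <- paste0("seed", seeds)
  sds <- apply(mat, 1, stats::sd)
  list(charges = mat, sd = sds,
       residualsBefore = vapply(runs, function(rn) rn$residualBefore,
                                numeric(1)),
       results = runs)
}

# ---- command-level functions ------------------------------------------------

.loadQuery <- function(query) {
  if (is(query, "MolecularGraph")) return(query)
  if (grepl("\\.(sdf|mol)$", query, ignore.case = TRUE))
    readMolecule(query, "sdf")
  else readMolecule(query, "smiles")
}

.loadLibrary <- function(lib) {
  if (is(lib, "FragmentLibrary")) return(lib)
  if (!file.exists(lib))
    stop("library file not found: ", lib, call. = FALSE)
  readFragmentLibrary(lib)
}

.matchReportList <- function(query, report) {
  list(
    query = report@queryName,
    k = report@k,
    n_atoms = nrow(query@atoms),
    n_fragments = length(report@matches),
    fragments = lapply(report@matches, function(mt) list(
      library_id = mt@libraryId,
      size = length(mt@queryAtoms),
      fragment_charge = if (is.na(mt@fragmentCharge)) NULL else
        round(mt@fragmentCharge, 4),
      query_atoms = mt@queryAtoms,
      ref_atoms = mt@refAtoms,
      shell_atoms = mt@shellAtoms)),
    atom_status = lapply(seq_along(report@atomIds), function(i) list(
      id = report@atomIds[i],
      element = query@atoms$element[i],
      status = if (report@coverage[i] > 0) "matched" else "missing",
      n_fragments = report@coverage[i]))
  )
}

#' Match command: rank library fragments against a query
#'
#' @param query \linkS4class{MolecularGraph}, SMILES string or SDF path
#' @param lib \linkS4class{FragmentLibrary} or JSON path
#' @param k shell size
#' @param out optional JSON output path
#' @param strict logical; error when any atom is unmatched
#' @return invisibly, the report as a list (also written to \code{out})
#' @export
cmdMatch <- function(query, lib, k = 3, out = NULL, strict = FALSE) {
  query <- .loadQuery(query)
  lib <- .loadLibrary(lib)
  report <- matchLibrary(query, lib, k)
  res <- .matchReportList(query, report)
  if (!is.null(out))
    jsonlite::write_json(res, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (strict && any(report@coverage == 0))
    stop("unmatched atom(s): ",
         paste(unmatchedAtoms(report), collapse = ", "), call. = FALSE)
  invisible(res)
}

#' Assign command: greedy charge assignment with optional multi-start
#'
#' One seed produces a charge set; several seeds additionally report the
#' per-atom standard deviation across starts. Charges are serialized at 4
#' decimal places; arithmetic is carried at full precision.
#'
#' @inheritParams greedyAssign
#' @param seeds integer vector; one greedy run per seed
#' @param out optional JSON output path
#' @param sdfOut optional path for an annotated SDF of the (first seed's)
#'   result
#' @return invisibly, the output list
#' @export
cmdAssign <- function(query, lib, k = 3, seeds = 1,
                      policy = c("average", "select"),
                      targetCharge = NULL, symmetrize = FALSE,
                      manualCharges = NULL, out = NULL, sdfOut = NULL) {
  policy <- match.arg(policy)
  query <- .loadQuery(query)
  lib <- .loadLibrary(lib)
  if (is.null(targetCharge)) targetCharge <- netCharge(query)
  report <- matchLibrary(query, lib, k)
  runs <- lapply(seeds, function(s)
    greedyAssign(query, lib, k, policy, targetCharge, seed = s,
                 symmetrize = symmetrize, manualCharges = manualCharges,
                 report = report))
  first <- runs[[1]]
  st <- first$state
  atomsOut <- lapply(seq_along(st@atomIds), function(i) {
    cands <- st@candidates[[i]]
    list(id = st@atomIds[i],
         element = query@atoms$element[i],
         charge = round(st@resolved[i], 4),
         provenance = cands$provenance,
         conflict_resolved_by =
           if (nrow(cands) > 1) policy else NULL)
  })
  res <- list(
    header = list(query = query@name, k = k,
                  target_charge = targetCharge,
                  residual_before = first$residualBefore,
                  residual_after = first$residualAfter,
                  policy = policy, seeds = seeds),
    atoms = atomsOut)
  if (length(seeds) > 1) {
    mat <- vapply(runs, function(rn) unname(rn$charges),
                  numeric(nrow(query@atoms)))
    sds <- apply(mat, 1, stats::sd)
    res$per_atom_sd <- lapply(seq_along(st@atomIds), function(i)
      list(id = st@atomIds[i], sd = sds[i]))
    res$residuals_before <- vapply(runs, function(rn)
      rn$residualBefore, numeric(1))
  }
  if (!is.null(out))
    jsonlite::write_json(res, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (!is.null(sdfOut)) {
    gOut <- query
    gOut@atoms$partial_charge <- st@resolved
    gOut@netCharge <- targetCharge
    writeSDF(gOut, sdfOut)
  }
  invisible(res)
}

#' Missing command: extract, split and cap unrepresented regions
#'
#' Finds atoms no library fragment covers, groups them with their k-shell
#' environment, splits oversized regions (ring-protected), caps each
#' piece, and writes an SDF of the capped molecules plus a JSON manifest
#' mapping fragment atoms back to query atom ids.
#'
#' @param query \linkS4class{MolecularGraph}, SMILES string or SDF path
#' @param lib \linkS4class{FragmentLibrary} or JSON path
#' @param k shell size
#' @param maxAtoms split limit for capped pieces
#' @param rules cap-rule table
#' @param sdfOut optional SDF output path (one record per capped piece)
#' @param manifestOut optional JSON manifest path
#' @return invisibly, list with \code{molecules} (capped
#'   \linkS4class{MolecularGraph}s) and \code{manifest}
#' @export
cmdMissing <- function(query, lib, k = 3, maxAtoms = 40,
                       rules = defaultCapRules(), sdfOut = NULL,
                       manifestOut = NULL) {
  query <- .loadQuery(query)
  lib <- .loadLibrary(lib)
  report <- matchLibrary(query, lib, k)
  un <- unmatchedAtoms(report)
  if (!length(un)) {
    message("no missing atoms: every query atom is covered")
    return(invisible(list(molecules = list(), manifest = list())))
  }
  frags <- groupMissing(query, un, k)
  pieces <- unlist(lapply(frags, function(f)
    splitFragment(query, f, maxAtoms)), recursive = FALSE)
  mols <- lapply(seq_along(pieces), function(i)
    capFragment(query, pieces[[i]], rules,
                name = sprintf("%s_missing%02d", query@name, i)))
  manifest <- lapply(seq_along(mols), function(i) {
    m <- mols[[i]]
    list(name = m@name,
         core_atoms = pieces[[i]]@coreAtoms,
         shell_atoms = pieces[[i]]@shellAtoms,
         atoms = lapply(seq_len(nrow(m@atoms)), function(j) list(
           sdf_position = j,
           query_id = if (m@atoms$cap[j]) NULL else m@atoms$id[j],
           cap = m@atoms$cap[j],
           element = m@atoms$element[j])))
  })
  if (!is.null(sdfOut)) {
    if (file.exists(sdfOut)) unlink(sdfOut)
    for (m in mols) writeSDF(m, sdfOut, append = TRUE)
  }
  if (!is.null(manifestOut))
    jsonlite::write_json(manifest, manifestOut, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  invisible(list(molecules = mols, manifest = manifest))
}
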