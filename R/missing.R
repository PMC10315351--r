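# Missing-fragment handling: group unmatched atoms with their shell,
# split oversized regions along acyclic bonds, and complete valences with
# neutral caps chosen by exact combinatorial optimisation.

#' Atoms not covered by any fragment
#'
#' @param report a \linkS4class{MatchReport}
#' @return integer vector of query atom ids covered by zero fragments
#' @export
unmatchedAtoms <- function(report) {
  stopifnot(is(report, "MatchReport"))
  report@atomIds[report@coverage == 0]
}

#' @rdname fragcharge-accessors
#' @export
setMethod("coreAtoms", "MissingFragment", function(x) x@coreAtoms)
#' @rdname fragcharge-accessors
#' @export
setMethod("shellAtoms", "MissingFragment", function(x) x@shellAtoms)

setMethod("show", "MissingFragment", function(object) {
  cat(sprintf(
    "MissingFragment: core %d atoms, shell %d atoms (k=%d), %d dangling\n",
    length(object@coreAtoms), length(object@shellAtoms), object@k,
    nrow(object@dangling)))
})

# per-atom valence target within a parent molecule: at least the element
# default, raised to the atom's actual bond-order sum in the parent (so
# hypervalent or deliberately unsaturated parents are honored)
.valenceTargets <- function(g) {
  tg <- .TARGET_VALENCE[g@atoms$element]
  tg[is.na(tg)] <- 0
  pmax(tg, .bondOrderSum(g))
}

# open valences of the atoms of `region` (atom ids) relative to the parent
.openValences <- function(g, region) {
  sub <- g@bonds[g@bonds$a1 %in% region & g@bonds$a2 %in% region, ,
                 drop = FALSE]
  inSum <- stats::setNames(numeric(length(region)), region)
  if (nrow(sub)) {
    ov <- .orderValue(sub$order)
    for (b in seq_len(nrow(sub))) {
      inSum[as.character(sub$a1[b])] <-
        inSum[as.character(sub$a1[b])] + ov[b]
      inSum[as.character(sub$a2[b])] <-
        inSum[as.character(sub$a2[b])] + ov[b]
    }
  }
  tg <- .valenceTargets(g)[match(region, g@atoms$id)]
  open <- tg - inSum
  data.frame(atom = as.integer(region), open = as.numeric(open))
}

.newMissingFragment <- function(g, core, region, k) {
  open <- .openValences(g, region)
  new("MissingFragment",
      coreAtoms = as.integer(sort(core)),
      shellAtoms = as.integer(sort(setdiff(region, core))),
      k = as.integer(k),
      dangling = open[open$open > 1e-9, , drop = FALSE])
}

#' Group unmatched atoms into missing fragments
#'
#' Cores are the connected components of the unmatched atom set; each is
#' extended by its k-shell (the local chemical environment that must
#' accompany the fragment). Fragments whose core-plus-shell regions share
#' atoms are merged, so no atom belongs to two output regions.
#'
#' @param g query \linkS4class{MolecularGraph}
#' @param unmatched integer vector of unmatched atom ids
#' @param k shell size
#' @return list of \linkS4class{MissingFragment}, ordered by smallest core
#'   atom id
#' @export
groupMissing <- function(g, unmatched, k = 3) {
  if (!length(unmatched)) return(list())
  .atomIndex(g, unmatched)
  ig <- .asIgraph(g)
  idx <- match(unmatched, g@atoms$id)
  sub <- igraph::induced_subgraph(ig, idx)
  comp <- igraph::components(sub)$membership
  cores <- split(unmatched, comp)
  d <- .distMatrix(g)
  regions <- lapply(cores, function(core) {
    ci <- match(core, g@atoms$id)
    ball <- which(colSums(d[ci, , drop = FALSE] <= k) > 0)
    sort(g@atoms$id[ball])
  })
  # merge fragments with overlapping regions (union-find)
  nf <- length(cores)
  parent <- seq_len(nf)
  findRoot <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  for (i in seq_len(nf)) for (j in seq_len(i - 1)) {
    if (length(intersect(regions[[i]], regions[[j]]))) {
      a <- findRoot(i); b <- findRoot(j)
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_len(nf), findRoot, integer(1))
  out <- lapply(unique(roots), function(rt) {
    members <- which(roots == rt)
    core <- sort(unlist(cores[members]))
    region <- sort(unique(unlist(regions[members])))
    .newMissingFragment(g, core, region, k)
  })
  out[order(vapply(out, function(f) min(f@coreAtoms), integer(1)))]
}

# capped size of a region: its atoms plus one hydrogen per open valence
# unit (the default, apolar capping)
.cappedSize <- function(g, region) {
  open <- .openValences(g, region)
  length(region) + sum(pmax(round(open$open), 0))
}

#' Split an oversized missing fragment along acyclic bonds
#'
#' Recursively divides the fragment region until each piece, including the
#' hydrogens capping will add, is within \code{maxAtoms}. Only bonds that
#' lie on no ring of the parent molecule are ever cut; at each step the
#' cut giving the most balanced pieces is chosen. A piece that cannot
#' shrink further without breaking a ring is returned whole even when
#' oversized.
#'
#' @param g parent \linkS4class{MolecularGraph}
#' @param frag a \linkS4class{MissingFragment}
#' @param maxAtoms size limit for the capped piece (default 40, targeting
#'   molecules of 30-40 atoms)
#' @return list of \linkS4class{MissingFragment} whose cores cover the
#'   input core
#' @export
splitFragment <- function(g, frag, maxAtoms = 40) {
  stopifnot(is(frag, "MissingFragment"))
  if (maxAtoms < 5)
    stop("maxAtoms must be at least 5 (smallest cappable unit)",
         call. = FALSE)
  region <- sort(c(frag@coreAtoms, frag@shellAtoms))
  ig <- .asIgraph(g)
  comp <- igraph::components(
    igraph::induced_subgraph(ig, match(region, g@atoms$id)))
  if (comp$no > 1)
    stop("fragment region is disconnected", call. = FALSE)
  bridgeEdges <- igraph::bridges(ig)
  bridgeKey <- apply(igraph::ends(ig, bridgeEdges), 1, function(e)
    paste(sort(g@atoms$id[as.integer(e)]), collapse = "-"))
  recurse <- function(core, region) {
    if (.cappedSize(g, region) <= maxAtoms)
      return(list(.newMissingFragment(g, core, region, frag@k)))
    bd <- g@bonds[g@bonds$a1 %in% region & g@bonds$a2 %in% region, ,
                  drop = FALSE]
    if (nrow(bd)) {
      keys <- paste(pmin(bd$a1, bd$a2), pmax(bd$a1, bd$a2), sep = "-")
      bd <- bd[keys %in% bridgeKey, , drop = FALSE]
    }
    if (!nrow(bd))  # ring-protected: no acyclic bond to cut
      return(list(.newMissingFragment(g, core, region, frag@k)))
    # pick the cut whose two sides are most balanced in capped size
    best <- NULL
    ridx <- match(region, g@atoms$id)
    subIg <- igraph::induced_subgraph(ig, ridx)
    for (b in seq_len(nrow(bd))) {
      v1 <- match(match(bd$a1[b], g@atoms$id), ridx)
      v2 <- match(match(bd$a2[b], g@atoms$id), ridx)
      cut <- igraph::delete_edges(subIg,
                                  igraph::get_edge_ids(subIg, c(v1, v2)))
      mem <- igraph::components(cut)$membership
      side1 <- region[mem == mem[v1]]
      side2 <- region[mem == mem[v2]]
      bal <- abs(.cappedSize(g, side1) - .cappedSize(g, side2))
      if (is.null(best) || bal < best$bal) {
        best <- list(bal = bal, side1 = side1, side2 = side2)
      }
    }
    c(recurse(intersect(core, best$side1), best$side1),
      recurse(intersect(core, best$side2), best$side2))
  }
  out <- recurse(frag@coreAtoms, region)
  out[order(vapply(out, function(f)
    min(c(f@coreAtoms, f@shellAtoms)), integer(1)))]
}

# ---- capping ----------------------------------------------------------------

#' Default capping rules
#'
#' Hydrogen-only caps: an atom with open valence v receives v hydrogens
#' (an aliphatic carbon is capped with 1, 2 or 3 hydrogens depending on
#' how many bonds it is missing). Caps are neutral and apolar, so they
#' introduce no net charge and no polar groups. Richer tables (e.g. with
#' methyl alternatives) can be loaded from a JSON config with
#' \code{\link{readCapRules}}.
#'
#' @return a cap-rule table: list of rules, each with \code{element}
#'   ("*" = any), \code{open} (NA = any open valence), and \code{options},
#'   a list of cap groups. A cap group is a data.frame with columns
#'   \code{element}, \code{attach} (0 = the capped atom, or the index of
#'   an earlier atom in the group) and \code{order}.
#' @export
defaultCapRules <- function() {
  list(list(element = "*", open = NA, options = NULL))
}

#' Read a capping-rule table from JSON
#'
#' Config format: \code{{"rules": [{"element": "C", "open": 1, "options":
#' [[{"element": "H", "attach": 0, "order": 1}], ...]}]}}; the built-in
#' hydrogen-only rule backs any case the config does not cover.
#'
#' @param path JSON config file
#' @return a cap-rule table (see \code{\link{defaultCapRules}})
#' @export
readCapRules <- function(path) {
  obj <- jsonlite::read_json(path)
  if (is.null(obj$rules))
    stop("cap-rule config lacks /rules", call. = FALSE)
  rules <- lapply(obj$rules, function(rl) {
    opts <- lapply(rl$options, function(op)
      do.call(rbind, lapply(op, function(a)
        data.frame(element = a$element, attach = as.integer(a$attach),
                   order = as.numeric(a$order)))))
    list(element = rl$element,
         open = if (is.null(rl$open)) NA else as.numeric(rl$open),
         options = opts)
  })
  c(rules, defaultCapRules())
}

# hydrogens-only option for open valence v
.hOption <- function(v) {
  v <- as.integer(round(v))
  data.frame(element = rep("H", v), attach = 0L, order = 1)
}

# option list for one dangling atom; errors when no rule applies
.capOptionsFor <- function(rules, element, open) {
  for (rl in rules) {
    if (!(rl$element %in% c("*", element))) next
    if (!is.na(rl$open) && abs(rl$open - open) > 1e-9) next
    opts <- if (is.null(rl$options)) list(.hOption(open)) else rl$options
    # keep options that complete the valence exactly
    opts <- Filter(function(op) {
      hostOrder <- sum(op$order[op$attach == 0])
      abs(hostOrder - open) < 1e-9
    }, opts)
    if (length(opts)) return(opts)
  }
  stop("no applicable capping rule for element ", element,
       " with open valence ", open, call. = FALSE)
}

# objective of one option: (heavy atoms added, hydrogens added)
.capCost <- function(op) {
  c(heavy = sum(op$element != "H"), hydrogens = sum(op$element == "H"))
}

# exact lexicographic optimisation over cap options: minimize total heavy
# cap atoms, then total hydrogens, by depth-first branch and bound with
# per-atom lower bounds (0-1 assignment variables, one option per atom)
.capOptimize <- function(optionSets) {
  nA <- length(optionSets)
  if (!nA) return(integer())
  costs <- lapply(optionSets, function(opts)
    t(vapply(opts, .capCost, numeric(2))))
  lbH <- vapply(costs, function(cm) min(cm[, 1]), numeric(1))
  lbHy <- vapply(costs, function(cm) min(cm[, 2]), numeric(1))
  best <- NULL
  bestCost <- c(Inf, Inf)
  lexLess <- function(a, b) a[1] < b[1] || (a[1] == b[1] && a[2] < b[2])
  choice <- integer(nA)
  dfs <- function(i, accH, accHy) {
    if (i > nA) {
      if (lexLess(c(accH, accHy), bestCost)) {
        bestCost <<- c(accH, accHy)
        best <<- choice
      }
      return(invisible())
    }
    bound <- c(accH + sum(lbH[i:nA]), accHy + sum(lbHy[i:nA]))
    if (!lexLess(bound, bestCost)) return(invisible())
    cm <- costs[[i]]
    for (oi in order(cm[, 1], cm[, 2])) {
      choice[i] <<- oi
      dfs(i + 1, accH + cm[oi, 1], accHy + cm[oi, 2])
    }
  }
  dfs(1, 0, 0)
  if (is.null(best))
    stop("capping optimisation found no feasible assignment",
         call. = FALSE)
  best
}

# reference implementation: exhaustive enumeration over all combinations
.capExhaustive <- function(optionSets) {
  nA <- length(optionSets)
  if (!nA) return(integer())
  grid <- expand.grid(lapply(optionSets, seq_along))
  costs <- apply(grid, 1, function(sel) {
    cs <- mapply(function(opts, oi) .capCost(opts[[oi]]),
                 optionSets, sel)
    rowSums(matrix(cs, nrow = 2))
  })
  ord <- order(costs[1, ], costs[2, ])
  as.integer(grid[ord[1], ])
}

#' Cap a missing fragment into a chemically complete molecule
#'
#' Builds the fragment's region (core plus shell) as a molecule and adds
#' neutral caps to every dangling valence. The combination of caps is
#' selected by an exact integer optimisation minimizing first the number
#' of heavy cap atoms, then the number of hydrogens, subject to exact
#' valence completion; caps carry formal charge 0 and, being terminal,
#' never alter ring structures. Cap atoms are flagged (\code{cap} column)
#' so downstream charge transfer ignores them; region atoms keep their
#' parent atom ids.
#'
#' @param g parent \linkS4class{MolecularGraph}
#' @param frag a \linkS4class{MissingFragment}
#' @param rules cap-rule table (default \code{\link{defaultCapRules}})
#' @param name molecule name for the capped output
#' @return a valence-complete \linkS4class{MolecularGraph}
#' @export
capFragment <- function(g, frag, rules = defaultCapRules(),
                        name = paste0(g@name, "_missing")) {
  region <- sort(c(frag@coreAtoms, frag@shellAtoms))
  at <- g@atoms[g@atoms$id %in% region, , drop = FALSE]
  bd <- g@bonds[g@bonds$a1 %in% region & g@bonds$a2 %in% region, ,
                drop = FALSE]
  at$partial_charge <- NA_real_
  dang <- .openValences(g, region)
  dang <- dang[dang$open > 1e-9, , drop = FALSE]
  optionSets <- lapply(seq_len(nrow(dang)), function(i) {
    el <- g@atoms$element[match(dang$atom[i], g@atoms$id)]
    .capOptionsFor(rules, el, dang$open[i])
  })
  sel <- .capOptimize(optionSets)
  nextId <- if (nrow(at)) max(at$id) + 1L else 0L
  for (i in seq_along(sel)) {
    op <- optionSets[[i]][[sel[i]]]
    ids <- nextId + seq_len(nrow(op)) - 1L
    nextId <- nextId + nrow(op)
    at <- rbind(at, data.frame(
      id = ids, element = op$element, formal_charge = 0L,
      partial_charge = NA_real_, x = NA_real_, y = NA_real_,
      z = NA_real_, cap = TRUE))
    hostIds <- ifelse(op$attach == 0, dang$atom[i], ids[op$attach])
    bd <- rbind(bd, data.frame(a1 = as.integer(hostIds), a2 = ids,
                               order = op$order))
  }
  out <- molecularGraph(at, bd, name = name, netCharge = 0)
  # capped molecules must be chemically complete
  tg <- .valenceTargets(g)
  targets <- stats::setNames(
    c(tg[match(region, g@atoms$id)],
      rep(NA, sum(out@atoms$cap))), out@atoms$id)
  capEls <- out@atoms$element[out@atoms$cap]
  targets[is.na(targets)] <- .TARGET_VALENCE[capEls]
  validateValence(out, targets = targets)
  if (sum(out@atoms$formal_charge[out@atoms$cap]) != 0)
    stop("caps introduced a net formal charge", call. = FALSE)
  out
}
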