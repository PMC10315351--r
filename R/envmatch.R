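# Environment-based atom compatibility and enumeration of all k-maximal
# common fragments between two molecules.
#
# Two atoms are equivalent only if the subgraphs induced by their k-balls
# (all atoms within k bonds) admit a root-preserving isomorphism in which
# every atom keeps its label (element, full-molecule degree). A common
# fragment is a connected, induced-subgraph-isomorphic set of such pairs
# whose core mapping extends to a single label- and adjacency-preserving
# witness on the union of the k-balls of its atoms; it is maximal when no
# single compatible adjacent pair can be added consistently.

# ---- matching context -------------------------------------------------------

# Precomputed per-pair matching data: adjacency, distances, shared integer
# labels, and per-atom environment signatures (label multiset per distance
# ring, a cheap necessary condition for compatibility).
.matchContext <- function(g1, g2, k) {
  mk <- function(g) {
    n <- nrow(g@atoms)
    adj <- matrix(FALSE, n, n)
    if (nrow(g@bonds)) {
      i1 <- match(g@bonds$a1, g@atoms$id)
      i2 <- match(g@bonds$a2, g@atoms$id)
      adj[cbind(i1, i2)] <- TRUE
      adj[cbind(i2, i1)] <- TRUE
    }
    list(g = g, n = n, adj = adj, dist = .distMatrix(g),
         labels = .labels(g), deg = .degrees(g), ig = .asIgraph(g))
  }
  e1 <- mk(g1)
  e2 <- mk(g2)
  lab <- unique(c(e1$labels, e2$labels))
  e1$labInt <- match(e1$labels, lab)
  e2$labInt <- match(e2$labels, lab)
  sig <- function(e) {
    vapply(seq_len(e$n), function(i) {
      d <- e$dist[i, ]
      rings <- vapply(0:k, function(r)
        paste(sort(e$labels[!is.infinite(d) & d == r]), collapse = ","),
        character(1))
      paste(rings, collapse = "|")
    }, character(1))
  }
  e1$sig <- sig(e1)
  e2$sig <- sig(e2)
  list(e1 = e1, e2 = e2, k = k, nLab = length(lab))
}

# Root-anchored ball isomorphism check (the definition of k-compatibility).
# Signatures must already agree; confirms with VF2 on the induced ball
# subgraphs, the roots pinned by a private color.
.ballIso <- function(ctx, i1, i2) {
  k <- ctx$k
  if (k == 0) return(TRUE)          # signature equality is the whole check
  b1 <- which(ctx$e1$dist[i1, ] <= k)
  b2 <- which(ctx$e2$dist[i2, ] <= k)
  if (length(b1) != length(b2)) return(FALSE)
  c1 <- ctx$e1$labInt[b1]
  c2 <- ctx$e2$labInt[b2]
  root <- ctx$nLab + 1L
  c1[b1 == i1] <- root
  c2[b2 == i2] <- root
  s1 <- igraph::induced_subgraph(ctx$e1$ig, b1)
  s2 <- igraph::induced_subgraph(ctx$e2$ig, b2)
  igraph::isomorphic(s1, s2, method = "vf2",
                     vertex.color1 = c1, vertex.color2 = c2)
}

#' Are two atoms k-compatible?
#'
#' TRUE iff there is a rooted isomorphism between the subgraphs induced by
#' the two atoms' k-balls that maps one atom onto the other and preserves
#' every atom's label (element and degree, degrees taken in the full
#' molecules). Symmetric in its arguments; monotone in k (compatible at k
#' implies compatible at every smaller shell size). At k = 0 it reduces to
#' label equality.
#'
#' @param g1,g2 \linkS4class{MolecularGraph}s
#' @param a1,a2 atom ids in \code{g1} and \code{g2}
#' @param k shell size (bonds)
#' @return logical
#' @examples
#' ph <- builtinMolecule("phenol")
#' atomsCompatible(ph, 0, ph, 0, 3)
#' @export
atomsCompatible <- function(g1, a1, g2, a2, k) {
  stopifnot(k >= 0)
  i1 <- .atomIndex(g1, a1)
  i2 <- .atomIndex(g2, a2)
  ctx <- .matchContext(g1, g2, k)
  if (ctx$e1$sig[i1] != ctx$e2$sig[i2]) return(FALSE)
  .ballIso(ctx, i1, i2)
}

# ---- consistency of a partial mapping --------------------------------------

# A candidate fragment {q_i -> r_i} is consistent when one injective map on
# the union of the k-balls of its core extends the core mapping, preserves
# labels, and preserves adjacency in both directions. Tries a cheap greedy
# forced-extension first (confirms most chemical cases), falls back to VF2
# with the core pinned pairwise by private colors.
.consistentWitness <- function(ctx, qs, rs) {
  k <- ctx$k
  if (k == 0) return(TRUE)  # ball union is the core; core map is a witness
  e1 <- ctx$e1; e2 <- ctx$e2
  b1 <- which(colSums(e1$dist[qs, , drop = FALSE] <= k) > 0)
  b2 <- which(colSums(e2$dist[rs, , drop = FALSE] <= k) > 0)
  if (length(b1) != length(b2)) return(FALSE)
  t1 <- sort(e1$labInt[b1]); t2 <- sort(e2$labInt[b2])
  if (!identical(t1, t2)) return(FALSE)

  # greedy forced extension from the core outward
  map <- rep(NA_integer_, e1$n)
  map[qs] <- rs
  used <- rep(FALSE, e2$n)
  used[rs] <- TRUE
  ok <- TRUE
  frontier <- qs
  inB1 <- rep(FALSE, e1$n); inB1[b1] <- TRUE
  inB2 <- rep(FALSE, e2$n); inB2[b2] <- TRUE
  while (length(frontier) && ok) {
    nxt <- integer()
    for (a in frontier) {
      nbrs <- which(e1$adj[a, ] & inB1 & is.na(map))
      for (b in nbrs) {
        if (!is.na(map[b])) next
        cand <- which(e2$adj[map[a], ] & inB2 & !used &
                        e2$labInt == e1$labInt[b])
        if (length(cand) == 0) { ok <- FALSE; break }
        map[b] <- cand[1]          # take first; verified below
        used[cand[1]] <- TRUE
        nxt <- c(nxt, b)
      }
      if (!ok) break
    }
    frontier <- nxt
  }
  if (ok && !anyNA(map[b1]) && !any(!used[b2])) {
    sub1 <- e1$adj[b1, b1, drop = FALSE]
    sub2 <- e2$adj[map[b1], map[b1], drop = FALSE]
    if (all(sub1 == sub2)) return(TRUE)
  }
  # ambiguous or greedy mis-stepped: decide exactly with VF2, cores pinned
  c1 <- e1$labInt[b1]
  c2 <- e2$labInt[b2]
  base <- ctx$nLab
  for (j in seq_along(qs)) {
    c1[b1 == qs[j]] <- base + j
    c2[b2 == rs[j]] <- base + j
  }
  s1 <- igraph::induced_subgraph(e1$ig, b1)
  s2 <- igraph::induced_subgraph(e2$ig, b2)
  igraph::isomorphic(s1, s2, method = "vf2",
                     vertex.color1 = c1, vertex.color2 = c2)
}

# ---- enumeration ------------------------------------------------------------

#' Enumerate all k-maximal common fragments between two molecules
#'
#' Builds the set of compatible atom pairs (see
#' \code{\link{atomsCompatible}}) and the pair product graph on it (two
#' pairs can coexist when they are injective and adjacency agrees in both
#' molecules; they are connectable when adjacent in both), then
#' enumerates maximal connected cliques with a Koch-style Bron-Kerbosch
#' recursion and verifies that each core mapping extends to a single
#' witness on the union of its atoms' k-balls. Interchangeable
#' terminal-atom pairings (e.g. the hydrogens of a methyl group) are
#' canonicalized during the recursion, and mappings sharing a query core
#' are collapsed to the lexicographically smallest, so symmetric images
#' are reported once.
#'
#' @param g1 query \linkS4class{MolecularGraph}
#' @param g2 reference \linkS4class{MolecularGraph}
#' @param k shell size (bonds)
#' @param libraryId id stored in the returned matches
#' @return list of \linkS4class{FragmentMatch}, ordered by size descending
#'   then lexicographically by query atom ids.
#' @examples
#' ph <- builtinMolecule("phenol")
#' pa <- builtinMolecule("paracetamol")
#' ms <- enumerateKMCF(ph, pa, 3)
#' fragmentSize(ms[[1]])  # 3
#' @export
enumerateKMCF <- function(g1, g2, k, libraryId = "") {
  stopifnot(k >= 0)
  ctx <- .matchContext(g1, g2, k)
  pairs <- .compatiblePairs(ctx)
  sets <- .enumerateMaximalSets(ctx, pairs)
  .buildMatches(ctx, pairs, sets, libraryId)
}

# all k-compatible atom pairs (internal 1-based indices)
.compatiblePairs <- function(ctx) {
  e1 <- ctx$e1; e2 <- ctx$e2
  bySig <- split(seq_len(e2$n), e2$sig)
  q <- integer(); r <- integer()
  for (i in seq_len(e1$n)) {
    cand <- bySig[[e1$sig[i]]]
    for (j in cand) {
      if (.ballIso(ctx, i, j)) {
        q <- c(q, i); r <- c(r, j)
      }
    }
  }
  list(q = q, r = r, m = length(q))
}

# Enumerate maximal consistent c-connected cliques of the pair product
# graph. Vertices are compatible atom pairs; two pairs are compatible
# (clique edges) when injective with agreeing adjacency, and c-adjacent
# when adjacent in both molecules. Maximal c-connected cliques are found
# with a Koch-style Bron-Kerbosch recursion; the (rare) cliques whose
# core mapping admits no shell witness are decomposed into their maximal
# consistent sub-mappings. Interchangeable terminal-twin pairings (e.g.
# methyl hydrogens) are canonicalized during the recursion so factorial
# families of symmetric images collapse to one representative.
.enumerateMaximalSets <- function(ctx, pairs) {
  m <- pairs$m
  if (m == 0) return(list())
  e1 <- ctx$e1; e2 <- ctx$e2
  q <- pairs$q; r <- pairs$r
  adjQ <- e1$adj[q, q, drop = FALSE]
  adjR <- e2$adj[r, r, drop = FALSE]
  compat <- !outer(q, q, "==") & !outer(r, r, "==") & (adjQ == adjR)
  leafQ <- e1$deg[q] == 1
  leafR <- e2$deg[r] == 1
  parentOf <- function(adj, a) {
    nb <- which(adj[a, ])
    if (length(nb) == 1) nb else NA_integer_
  }
  parentQ <- ifelse(leafQ, vapply(q, function(a) parentOf(e1$adj, a),
                                  integer(1)), NA_integer_)
  parentR <- ifelse(leafR, vapply(r, function(a) parentOf(e2$adj, a),
                                  integer(1)), NA_integer_)
  # Terminal-twin canonicalization: pairs drawn from one twin group (same
  # parent on each side, e.g. the hydrogens of one methyl matched to the
  # hydrogens of another) may only co-occur order-preservingly, so of the
  # factorially many interchangeable matchings exactly the sorted one -
  # which is the lexicographically smallest - survives as a clique.
  compatFull <- compat
  cEdgeFull <- compatFull & adjQ
  # Terminal-twin canonicalization. Twin atoms (degree-1 children of one
  # parent with one label, e.g. methyl hydrogens) are interchangeable:
  # their k-balls are identical. Of the factorially many matchings
  # between a query twin group and a reference twin group only one
  # representative is enumerated; outputs are later remapped to the
  # lexicographically smallest pairing, so nothing observable is lost.
  excluded <- rep(FALSE, m)
  tw <- which(leafQ & leafR & !is.na(parentQ) & !is.na(parentR))
  if (length(tw)) {
    rankIn <- function(adj, deg, lab, atoms, parents) {
      rk <- integer(length(atoms)); sz <- integer(length(atoms))
      for (i in seq_along(atoms)) {
        sibs <- which(adj[parents[i], ] & deg == 1 & lab == lab[atoms[i]])
        rk[i] <- match(atoms[i], sort(sibs))
        sz[i] <- length(sibs)
      }
      list(rank = rk, size = sz)
    }
    qr <- rankIn(e1$adj, e1$deg, e1$labInt, q[tw], parentQ[tw])
    rr <- rankIn(e2$adj, e2$deg, e2$labInt, r[tw], parentR[tw])
    # equal-size groups: a maximal mapping pairs the groups completely,
    # so only rank-aligned pair vertices are needed
    excluded[tw[qr$size == rr$size & qr$rank != rr$rank]] <- TRUE
    compat[excluded, ] <- FALSE
    compat[, excluded] <- FALSE
    # unequal-size groups: partial matchings are real, but only the
    # order-preserving ones need enumerating
    twk <- tw[!excluded[tw]]
    if (length(twk) > 1) {
      labQ <- e1$labInt[q]
      sameGrp <- outer(parentQ[twk], parentQ[twk], "==") &
        outer(parentR[twk], parentR[twk], "==") &
        outer(labQ[twk], labQ[twk], "==")
      orderOK <- outer(q[twk], q[twk], "<") == outer(r[twk], r[twk], "<")
      bad <- sameGrp & !orderOK &
        !outer(q[twk], q[twk], "==") & !outer(r[twk], r[twk], "==")
      compat[twk, twk][bad] <- FALSE
    }
  }
  cEdge <- compat & adjQ

  consMemo <- new.env(hash = TRUE, parent = emptyenv())
  consistent <- function(S) {
    S <- sort(S)
    key <- paste(S, collapse = ",")
    hit <- consMemo[[key]]
    if (!is.null(hit)) return(hit)
    val <- .consistentWitness(ctx, q[S], r[S])
    consMemo[[key]] <- val
    val
  }

  # Maximal c-connected cliques via a decomposition: every maximal
  # c-connected clique is the c-component containing it of any maximal
  # plain clique it extends to (a vertex of that clique c-adjacent to it
  # and compatible with all of it would contradict its maximality).
  # Plain maximal cliques are enumerated with igraph's pivoted
  # Bron-Kerbosch, restricted to one c-component of the pair graph at a
  # time so that independent symmetric regions do not multiply.
  cGraph <- igraph::graph_from_adjacency_matrix(cEdge, mode = "undirected")
  cMember <- igraph::components(cGraph)$membership
  seen <- new.env(hash = TRUE, parent = emptyenv())
  cliques <- list()
  for (comp in unique(cMember)) {
    verts <- which(cMember == comp)
    if (length(verts) == 1) {
      if (excluded[verts]) next
      key <- as.character(verts)
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        cliques[[length(cliques) + 1]] <- verts
      }
      next
    }
    sub <- igraph::graph_from_adjacency_matrix(
      compat[verts, verts, drop = FALSE], mode = "undirected")
    for (cl in igraph::max_cliques(sub)) {
      mc <- verts[as.integer(cl)]
      # split the clique into its c-connected components
      subC <- igraph::components(igraph::graph_from_adjacency_matrix(
        cEdge[mc, mc, drop = FALSE], mode = "undirected"))$membership
      for (cc in unique(subC)) {
        K <- sort(mc[subC == cc])
        # K must be inextensible as a c-connected clique
        ext <- which(rowSums(compat[, K, drop = FALSE]) == length(K) &
                       rowSums(cEdge[, K, drop = FALSE]) > 0)
        if (length(setdiff(ext, K))) next
        key <- paste(K, collapse = ",")
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          cliques[[length(cliques) + 1]] <- K
        }
      }
    }
  }

  # consistency: cliques whose core map has no shell witness decompose
  # into their maximal consistent c-connected sub-mappings; every
  # candidate must then survive a maximality check against the full
  # (untruncated) pair graph - a set a consistent pair can still extend
  # is not maximal, its completion is reported elsewhere
  unextendable <- function(S) {
    ext <- which(rowSums(compatFull[, S, drop = FALSE]) == length(S) &
                   rowSums(cEdgeFull[, S, drop = FALSE]) > 0)
    ext <- setdiff(ext, S)
    !any(vapply(ext, function(p) consistent(c(S, p)), logical(1)))
  }
  out <- list()
  for (K in cliques) {
    if (consistent(K)) {
      if (unextendable(K)) out[[length(out) + 1]] <- sort(K)
    } else {
      subs <- .maximalConsistentWithin(K, compat, cEdge, consistent)
      for (S in subs) {
        if (unextendable(S)) out[[length(out) + 1]] <- sort(S)
      }
    }
  }
  out <- unique(out)
  # drop sets that are sub-mappings of other results
  if (length(out) > 1) {
    out <- out[order(-lengths(out))]
    keep <- rep(TRUE, length(out))
    for (i in seq_along(out)) {
      if (!keep[i]) next
      for (j in seq_len(i - 1)) {
        if (keep[j] && all(out[[i]] %in% out[[j]])) {
          keep[i] <- FALSE
          break
        }
      }
    }
    out <- out[keep]
  }
  out
}

# maximal consistent c-connected subsets of an inconsistent clique K:
# exhaustive growth restricted to K (K is small and the case is rare)
.maximalConsistentWithin <- function(K, compat, cEdge, consistent,
                                     maxStates = 262144) {
  visited <- new.env(hash = TRUE, parent = emptyenv())
  found <- list()
  n <- 0L
  grow <- function(S) {
    n <<- n + 1L
    if (n > maxStates)
      stop("inconsistent-clique decomposition exceeded ", maxStates,
           " states", call. = FALSE)
    cand <- K[!(K %in% S)]
    cand <- cand[vapply(cand, function(p)
      any(cEdge[p, S]), logical(1))]
    grew <- FALSE
    for (p in cand) {
      S2 <- sort(c(S, p))
      if (!consistent(S2)) next
      grew <- TRUE
      key <- paste(S2, collapse = ",")
      if (is.null(visited[[key]])) {
        visited[[key]] <- TRUE
        grow(S2)
      }
    }
    if (!grew) found[[length(found) + 1]] <<- S
  }
  for (p in K) grow(p)
  unique(found)
}

# Remap the reference side of terminal-twin pairs to the smallest
# siblings: the canonical representative of the interchangeable twin
# matchings (output normalization; shared contract with the oracle).
.canonTwinRemap <- function(adj1, deg1, lab1, adj2, deg2, lab2, qi, ri) {
  isL <- deg1[qi] == 1 & deg2[ri] == 1
  if (!any(isL)) return(ri)
  p1 <- rep(NA_integer_, length(qi))
  p2 <- rep(NA_integer_, length(ri))
  p1[isL] <- vapply(qi[isL], function(a) which(adj1[a, ])[1], integer(1))
  p2[isL] <- vapply(ri[isL], function(a) which(adj2[a, ])[1], integer(1))
  grp <- ifelse(isL, paste(p1, p2, lab1[qi], sep = ":"), NA)
  for (gk in unique(grp[isL])) {
    idx <- which(!is.na(grp) & grp == gk)
    sibs <- sort(which(adj2[p2[idx[1]], ] & deg2 == 1 &
                         lab2 == lab1[qi[idx[1]]]))
    ri[idx[order(qi[idx])]] <- sibs[seq_along(idx)]
  }
  ri
}

# Collapse mappings sharing a query core to the lexicographically smallest
# mapping, build FragmentMatch objects, order deterministically.
.buildMatches <- function(ctx, pairs, sets, libraryId) {
  if (!length(sets)) return(list())
  e1 <- ctx$e1; e2 <- ctx$e2
  k <- ctx$k
  recs <- lapply(sets, function(S) {
    ord <- order(pairs$q[S])
    qi <- pairs$q[S][ord]
    ri <- .canonTwinRemap(e1$adj, e1$deg, e1$labInt,
                          e2$adj, e2$deg, e2$labInt,
                          qi, pairs$r[S][ord])
    list(qi = qi, ri = ri)
  })
  coreKey <- vapply(recs, function(x) paste(x$qi, collapse = ","),
                    character(1))
  chosen <- list()
  for (i in seq_along(recs)) {
    keyI <- coreKey[i]
    prev <- chosen[[keyI]]
    if (is.null(prev)) {
      chosen[[keyI]] <- recs[[i]]
    } else {
      # lexicographic comparison of aligned reference id vectors
      a <- recs[[i]]$ri; b <- prev$ri
      d <- which(a != b)
      if (length(d) && a[d[1]] < b[d[1]]) chosen[[keyI]] <- recs[[i]]
    }
  }
  refCharges <- e2$g@atoms$partial_charge
  refCap <- e2$g@atoms$cap
  qIds <- e1$g@atoms$id
  rIds <- e2$g@atoms$id
  out <- lapply(chosen, function(x) {
    ball <- unique(unlist(lapply(x$qi, function(i)
      which(e1$dist[i, ] <= k))))
    shell <- sort(qIds[setdiff(ball, x$qi)])
    nonCap <- !refCap[x$ri]
    fc <- if (anyNA(refCharges[x$ri][nonCap])) NA_real_ else
      sum(refCharges[x$ri][nonCap])
    new("FragmentMatch", libraryId = libraryId,
        queryAtoms = as.integer(qIds[x$qi]),
        refAtoms = as.integer(rIds[x$ri]),
        k = as.integer(k), shellAtoms = as.integer(shell),
        fragmentCharge = fc)
  })
  names(out) <- NULL
  .orderMatches(out)
}

# deterministic ranking: size descending, then library id, then query ids
.orderMatches <- function(matches) {
  if (!length(matches)) return(matches)
  keys <- vapply(matches, function(mt)
    paste(sprintf("%06d", 999999L - length(mt@queryAtoms)), mt@libraryId,
          paste(sprintf("%06d", mt@queryAtoms), collapse = ","),
          sep = "|"), character(1))
  matches[order(keys)]
}

# ---- accessors / show -------------------------------------------------------

#' @rdname fragcharge-accessors
#' @export
setMethod("queryAtoms", "FragmentMatch", function(x) x@queryAtoms)
#' @rdname fragcharge-accessors
#' @export
setMethod("refAtoms", "FragmentMatch", function(x) x@refAtoms)
#' @rdname fragcharge-accessors
#' @export
setMethod("shellAtoms", "FragmentMatch", function(x) x@shellAtoms)
#' @rdname fragcharge-accessors
#' @export
setMethod("fragmentSize", "FragmentMatch", function(x) length(x@queryAtoms))
#' @rdname fragcharge-accessors
#' @export
setMethod("fragmentCharge", "FragmentMatch", function(x) x@fragmentCharge)
#' @rdname fragcharge-accessors
#' @export
setMethod("libraryId", "FragmentMatch", function(x) x@libraryId)

setMethod("show", "FragmentMatch", function(object) {
  cat(sprintf(
    "FragmentMatch: %d atoms (k=%d)%s, charge %s\n  query %s -> ref %s\n",
    length(object@queryAtoms), object@k,
    if (nzchar(object@libraryId)) paste0(" vs ", object@libraryId) else "",
    if (is.na(object@fragmentCharge)) "NA" else
      sprintf("%.4f e", object@fragmentCharge),
    paste(object@queryAtoms, collapse = ","),
    paste(object@refAtoms, collapse = ",")))
})

# ---- library-wide matching --------------------------------------------------

#' Match a query molecule against a fragment library
#'
#' Enumerates all k-maximal common fragments between the query and every
#' library entry, ranks them by the extent of overlap with the query
#' (number of atoms, descending; ties broken by library id then query atom
#' ids), and records for every query atom whether at least one fragment
#' covers it through a non-cap reference atom. Each fragment reports its
#' total reference charge.
#'
#' @param query \linkS4class{MolecularGraph}
#' @param lib \linkS4class{FragmentLibrary}
#' @param k shell size (default 3)
#' @return a \linkS4class{MatchReport}
#' @export
matchLibrary <- function(query, lib, k = 3) {
  stopifnot(is(lib, "FragmentLibrary"))
  if (!length(lib@entries)) stop("empty fragment library", call. = FALSE)
  all <- list()
  for (id in names(lib@entries)) {
    all <- c(all, enumerateKMCF(query, lib@entries[[id]], k,
                                libraryId = id))
  }
  all <- .orderMatches(all)
  cov <- integer(nrow(query@atoms))
  for (mt in all) {
    entry <- lib@entries[[mt@libraryId]]
    nonCap <- !entry@atoms$cap[match(mt@refAtoms, entry@atoms$id)]
    idx <- match(mt@queryAtoms[nonCap], query@atoms$id)
    cov[idx] <- cov[idx] + 1L
  }
  new("MatchReport", matches = all, coverage = cov,
      atomIds = as.integer(query@atoms$id), k = as.integer(k),
      queryName = query@name)
}

#' @rdname fragcharge-accessors
#' @export
setMethod("matches", "MatchReport", function(x) x@matches)
#' @rdname fragcharge-accessors
#' @export
setMethod("coverage", "MatchReport", function(x) x@coverage)

setMethod("show", "MatchReport", function(object) {
  cat(sprintf(
    "MatchReport for '%s' (k=%d): %d fragments, %d/%d atoms matched\n",
    object@queryName, object@k, length(object@matches),
    sum(object@coverage > 0), length(object@coverage)))
  for (mt in utils::head(object@matches, 5)) show(mt)
  if (length(object@matches) > 5) cat("  ...\n")
})
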