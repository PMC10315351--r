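# Brute-force enumeration oracle for k-maximal common fragments.
#
# Semantically identical contract to enumerateKMCF, implemented from the
# definitions with none of its machinery: hand-rolled breadth-first
# distances, backtracking rooted-isomorphism checks, backtracking witness
# search for consistency, and exhaustive breadth-first growth over all
# connected consistent pair sets. Intended for small instances only.

.bfAdj <- function(g) {
  n <- nrow(g@atoms)
  adj <- matrix(FALSE, n, n)
  if (nrow(g@bonds)) {
    i1 <- match(g@bonds$a1, g@atoms$id)
    i2 <- match(g@bonds$a2, g@atoms$id)
    for (b in seq_along(i1)) {
      adj[i1[b], i2[b]] <- TRUE
      adj[i2[b], i1[b]] <- TRUE
    }
  }
  adj
}

.bfDistances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in which(adj[v, ])) {
        if (is.infinite(d[s, w])) {
          d[s, w] <- d[s, v] + 1
          queue <- c(queue, w)
        }
      }
    }
  }
  d
}

# backtracking injective map of set b1 onto set b2 extending `fixed`
# (named int vector b1atom -> b2atom), preserving labels and adjacency in
# both directions; returns TRUE when one exists
.bfExtendMap <- function(adj1, lab1, b1, adj2, lab2, b2, fixed) {
  todo <- setdiff(b1, as.integer(names(fixed)))
  # order: atoms adjacent to already-fixed atoms first (keeps search tight)
  ordItems <- integer()
  pool <- todo
  anchor <- as.integer(names(fixed))
  while (length(pool)) {
    nxt <- pool[vapply(pool, function(v)
      any(adj1[v, c(anchor, ordItems)]), logical(1))]
    if (!length(nxt)) nxt <- pool[1]
    ordItems <- c(ordItems, nxt[1])
    pool <- setdiff(pool, nxt[1])
  }
  assign_ <- as.list(fixed)
  names(assign_) <- names(fixed)
  recur <- function(pos) {
    if (pos > length(ordItems)) return(TRUE)
    v <- ordItems[pos]
    doneB1 <- as.integer(names(assign_))
    usedB2 <- as.integer(unlist(assign_))
    for (w in setdiff(b2, usedB2)) {
      if (lab2[w] != lab1[v]) next
      okAdj <- all(adj1[v, doneB1] == adj2[w, usedB2])
      if (!okAdj) next
      assign_[[as.character(v)]] <<- w
      if (recur(pos + 1)) return(TRUE)
      assign_[[as.character(v)]] <<- NULL
    }
    FALSE
  }
  recur(1)
}

#' Brute-force enumeration of k-maximal common fragments (test oracle)
#'
#' Exhaustively grows every connected set of compatible atom pairs and
#' keeps the maximal consistent ones. Same contract as
#' \code{\link{enumerateKMCF}} but implemented independently from the
#' definitions; refuses instances with more than ~400 atom-pair
#' combinations.
#'
#' @inheritParams enumerateKMCF
#' @return list of \linkS4class{FragmentMatch}
#' @export
bruteForceKMCF <- function(g1, g2, k, libraryId = "") {
  stopifnot(k >= 0)
  n1 <- nrow(g1@atoms); n2 <- nrow(g2@atoms)
  if (n1 * n2 > 400)
    stop("instance too large for the brute-force oracle: ", n1, " x ", n2,
         " = ", n1 * n2, " atom pairs (limit 400)", call. = FALSE)
  adj1 <- .bfAdj(g1); adj2 <- .bfAdj(g2)
  d1 <- .bfDistances(adj1); d2 <- .bfDistances(adj2)
  deg1 <- rowSums(adj1); deg2 <- rowSums(adj2)
  lab1 <- paste0(g1@atoms$element, "/", deg1)
  lab2 <- paste0(g2@atoms$element, "/", deg2)

  ballOf1 <- lapply(seq_len(n1), function(i) which(d1[i, ] <= k))
  ballOf2 <- lapply(seq_len(n2), function(i) which(d2[i, ] <= k))

  pairOK <- function(i, j) {
    if (lab1[i] != lab2[j]) return(FALSE)
    b1 <- ballOf1[[i]]; b2 <- ballOf2[[j]]
    if (length(b1) != length(b2)) return(FALSE)
    .bfExtendMap(adj1, lab1, b1, adj2, lab2, b2,
                 stats::setNames(j, i))
  }
  q <- integer(); r <- integer()
  for (i in seq_len(n1)) for (j in seq_len(n2))
    if (pairOK(i, j)) { q <- c(q, i); r <- c(r, j) }
  m <- length(q)
  if (m == 0) return(list())

  consMemo <- new.env(hash = TRUE, parent = emptyenv())
  consistent <- function(S) {
    key <- paste(S, collapse = ",")
    hit <- consMemo[[key]]
    if (!is.null(hit)) return(hit)
    qs <- q[S]; rs <- r[S]
    b1 <- sort(unique(unlist(ballOf1[qs])))
    b2 <- sort(unique(unlist(ballOf2[rs])))
    val <- if (length(b1) != length(b2)) FALSE else
      .bfExtendMap(adj1, lab1, b1, adj2, lab2, b2,
                   stats::setNames(rs, qs))
    consMemo[[key]] <- val
    val
  }
  compatM <- matrix(FALSE, m, m)
  cM <- matrix(FALSE, m, m)
  for (p1 in seq_len(m)) for (p2 in seq_len(m)) {
    if (p1 == p2) next
    compatM[p1, p2] <- q[p1] != q[p2] && r[p1] != r[p2] &&
      adj1[q[p1], q[p2]] == adj2[r[p1], r[p2]]
    cM[p1, p2] <- adj1[q[p1], q[p2]] && adj2[r[p1], r[p2]]
  }

  # breadth-first closure over ALL c-connected cliques of the pair graph
  # (no consistency filtering during growth), then keep the consistent
  # sets with no consistent single-pair extension
  visited <- new.env(hash = TRUE, parent = emptyenv())
  allSets <- list()
  queue <- as.list(seq_len(m))
  for (p in seq_len(m)) visited[[as.character(p)]] <- TRUE
  while (length(queue)) {
    S <- queue[[1]]; queue <- queue[-1]
    allSets[[length(allSets) + 1]] <- S
    for (p in setdiff(seq_len(m), S)) {
      if (!all(compatM[p, S])) next
      if (!any(cM[p, S])) next
      S2 <- sort(c(S, p))
      key <- paste(S2, collapse = ",")
      if (is.null(visited[[key]])) {
        visited[[key]] <- TRUE
        queue[[length(queue) + 1]] <- S2
      }
    }
  }
  maximal <- list()
  for (S in allSets) {
    if (!consistent(S)) next
    cand <- setdiff(seq_len(m), S)
    cand <- cand[vapply(cand, function(p)
      all(compatM[p, S]) && any(cM[p, S]), logical(1))]
    extendable <- any(vapply(cand, function(p)
      consistent(sort(c(S, p))), logical(1)))
    if (!extendable) maximal[[length(maximal) + 1]] <- S
  }
  # drop sub-mappings of other maximal results
  if (length(maximal) > 1) {
    ord <- order(-lengths(maximal))
    maximal <- maximal[ord]
    keep <- rep(TRUE, length(maximal))
    for (i in seq_along(maximal)) {
      if (!keep[i]) next
      for (jj in seq_len(i - 1)) {
        if (keep[jj] && all(maximal[[i]] %in% maximal[[jj]])) {
          keep[i] <- FALSE; break
        }
      }
    }
    maximal <- maximal[keep]
  }
  # canonicalize interchangeable twin pairings, then collapse by query
  # core keeping the lexicographically smallest mapping
  recs <- lapply(maximal, function(S) {
    ord <- order(q[S])
    qi <- q[S][ord]
    ri <- .canonTwinRemap(adj1, deg1, lab1, adj2, deg2, lab2,
                          qi, r[S][ord])
    list(qi = qi, ri = ri)
  })
  chosen <- list()
  for (rec in recs) {
    keyI <- paste(rec$qi, collapse = ",")
    prev <- chosen[[keyI]]
    if (is.null(prev)) {
      chosen[[keyI]] <- rec
    } else {
      d <- which(rec$ri != prev$ri)
      if (length(d) && rec$ri[d[1]] < prev$ri[d[1]]) chosen[[keyI]] <- rec
    }
  }
  qIds <- g1@atoms$id; rIds <- g2@atoms$id
  refCharges <- g2@atoms$partial_charge
  refCap <- g2@atoms$cap
  out <- lapply(chosen, function(x) {
    ball <- sort(unique(unlist(ballOf1[x$qi])))
    shell <- sort(qIds[setdiff(ball, x$qi)])
    nonCap <- !refCap[x$ri]
    fc <- if (anyNA(refCharges[x$ri][nonCap])) NA_real_ else
      sum(refCharges[x$ri][nonCap])
    new("FragmentMatch", libraryId = libraryId,
        queryAtoms = as.integer(qIds[x$qi]),
        refAtoms = as.integer(rIds[x$ri]),
        k = as.integer(k),
        shellAtoms = as.integer(shell), fragmentCharge = fc)
  })
  names(out) <- NULL
  .orderMatches(out)
}
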