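#' @include AllClasses.R
NULL

## Maximum cardinality search on an adjacency matrix. Returns the visit
## order and whether the graph is chordal (Tarjan-Yannakakis test: for each
## vertex, its earlier-visited neighbours minus the latest-visited of them
## must all be adjacent to that latest one).
.mcs <- function(adj) {
  nv <- nrow(adj)
  order <- integer(nv)
  visited <- rep(FALSE, nv)
  weight <- integer(nv)
  for (i in seq_len(nv)) {
    cand <- which(!visited)
    v <- cand[which.max(weight[cand])]
    order[i] <- v
    visited[v] <- TRUE
    nb <- which(adj[v, ] == 1L & !visited)
    weight[nb] <- weight[nb] + 1L
  }
  rank <- integer(nv)
  rank[order] <- seq_len(nv)
  chordal <- TRUE
  for (i in seq_len(nv)) {
    v <- order[i]
    prev <- which(adj[v, ] == 1L)
    prev <- prev[rank[prev] < i]
    if (length(prev) > 1L) {
      m <- prev[which.max(rank[prev])]
      rest <- setdiff(prev, m)
      if (any(adj[m, rest] == 0L)) {
        chordal <- FALSE
        break
      }
    }
  }
  list(order = order, rank = rank, chordal = chordal)
}

.maximalCliques <- function(adj) {
  nv <- nrow(adj)
  ## brute force over vertex subsets; fine for the k <= 5 graphs used here
  subsets <- lapply(seq_len(2^nv - 1L), function(s) {
    which(bitwAnd(bitwShiftR(s, seq_len(nv) - 1L), 1L) == 1L)
  })
  complete <- vapply(subsets, function(S) {
    if (length(S) < 2L) return(TRUE)
    all(adj[S, S][upper.tri(diag(length(S)))] == 1L)
  }, logical(1))
  cls <- subsets[complete]
  maximal <- vapply(seq_along(cls), function(i) {
    !any(vapply(seq_along(cls), function(j) {
      j != i && length(cls[[i]]) < length(cls[[j]]) &&
        all(cls[[i]] %in% cls[[j]])
    }, logical(1)))
  }, logical(1))
  cls[maximal]
}

## Clique/separator decomposition of a chordal graph: order the maximal
## cliques by the highest MCS rank of their members; the separator of each
## clique is its intersection with the union of the earlier ones (running
## intersection property). Empty separators join the components of the
## junction forest and are kept with multiplicity.
.decompose <- function(adj, mcs = .mcs(adj)) {
  cliques <- .maximalCliques(adj)
  maxRank <- vapply(cliques, function(C) max(mcs$rank[C]), numeric(1))
  cliques <- cliques[order(maxRank)]
  seps <- list()
  if (length(cliques) > 1L) {
    for (i in 2:length(cliques)) {
      hist <- unique(unlist(cliques[seq_len(i - 1L)]))
      seps[[i - 1L]] <- sort(intersect(cliques[[i]], hist))
    }
  }
  list(cliques = cliques, separators = seps)
}

.modelLabel <- function(cliques) {
  paste0(vapply(cliques, function(C)
    paste0("[", paste(C, collapse = ","), "]"), character(1)), collapse = "")
}

#' Enumerate decomposable dependence models
#'
#' Lists every labeled chordal (decomposable) graph on the \eqn{k} encounter
#' events, each with a clique/separator decomposition satisfying the running
#' intersection property. These are the dependence structures whose
#' hyper-Dirichlet marginal likelihood is available in closed form, and the
#' model space averaged over by \code{\link{bmaPosterior}}. There are 8, 61
#' and 822 such models for \eqn{k = 3, 4, 5}.
#'
#' @param k number of encounter events, between 3 and 5 (the enumeration
#'   grows super-exponentially beyond that).
#' @return List of \linkS4class{DecomposableModel} objects in a deterministic
#'   order (by number of edges, then by edge code).
#' @examples
#' length(enumerateDecomposableModels(3))  # 8
#' @export
enumerateDecomposableModels <- function(k) {
  k <- as.integer(k)
  if (k < 3L || k > 5L) {
    crcStop("k must be between 3 and 5 (model enumeration explodes beyond 5 lists)")
  }
  pairs <- utils::combn(k, 2L)
  ne <- ncol(pairs)
  out <- list()
  for (code in 0:(2^ne - 1L)) {
    sel <- which(bitwAnd(bitwShiftR(code, seq_len(ne) - 1L), 1L) == 1L)
    adj <- matrix(0L, k, k)
    for (e in sel) {
      adj[pairs[1L, e], pairs[2L, e]] <- 1L
      adj[pairs[2L, e], pairs[1L, e]] <- 1L
    }
    mcs <- .mcs(adj)
    if (!mcs$chordal) next
    dec <- .decompose(adj, mcs)
    edges <- t(pairs[, sel, drop = FALSE])
    colnames(edges) <- c("a", "b")
    out[[length(out) + 1L]] <- new("DecomposableModel",
      k = k, edges = edges, cliques = dec$cliques,
      separators = dec$separators, label = .modelLabel(dec$cliques))
  }
  nEdges <- vapply(out, function(m) nrow(m@edges), integer(1))
  codes <- vapply(out, function(m) {
    if (nrow(m@edges) == 0L) return(0)
    sum(2^(match(paste(m@edges[, 1L], m@edges[, 2L]),
                 paste(pairs[1L, ], pairs[2L, ])) - 1))
  }, numeric(1))
  out[order(nEdges, codes)]
}

setMethod("show", "DecomposableModel", function(object) {
  cat(sprintf("DecomposableModel on %d events: %s (%d edges)\n",
              object@k, object@label, nrow(object@edges)))
})
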