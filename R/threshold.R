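#' Binarize a weighted connectome at its K strongest edges
#'
#' Retains exactly the K largest positive weights as unweighted edges.
#' Weighted brain networks are binarized this way to emphasize strong
#' interactions and to give every subject the same edge count, since most
#' graph measures are highly sensitive to density. Ties at the cut are broken
#' deterministically: among equal weights, pairs earlier in ascending
#' lexicographic node order are retained first.
#'
#' @param x a [WeightedConnectome-class] or a numeric symmetric matrix.
#' @param k number of edges to keep; must satisfy 1 <= k <= number of
#'   strictly positive weights.
#' @return a [BinaryNetwork-class] with exactly \code{k} edges.
#' @export
#' @examples
#' w <- matrix(0, 4, 4); w[1, 2] <- w[2, 1] <- 3; w[3, 4] <- w[4, 3] <- 1
#' net <- binarizeTopK(w, 1)
#' edgeMatrix(net)  # keeps only the strongest pair (1,2)
binarizeTopK <- function(x, k) {
  w <- if (is(x, "WeightedConnectome")) x@weights else x
  n <- nrow(w)
  pr <- allPairs(n)
  wt <- w[pr]
  pos <- which(wt > 0)
  if (k < 1L || k > length(pos))
    stop("k must be between 1 and the number of strictly positive weights (",
         length(pos), ")")
  # pairs are already in ascending lexicographic order; a stable sort on
  # decreasing weight therefore retains lower pairs first on ties
  keep <- pos[order(-wt[pos])[seq_len(k)]]
  keep <- sort(keep)
  new("BinaryNetwork", nNodes = as.integer(n),
      edges = pr[keep, , drop = FALSE])
}

#' @rdname asIgraph
#' @export
setMethod("asIgraph", "BinaryNetwork", function(x) {
  g <- igraph::make_empty_graph(n = x@nNodes, directed = FALSE)
  if (nrow(x@edges)) g <- igraph::add_edges(g, t(x@edges))
  g
})

binaryFromIgraph <- function(g, n = igraph::vcount(g)) {
  el <- igraph::as_edgelist(g, names = FALSE)
  storage.mode(el) <- "integer"
  if (nrow(el)) {
    el <- cbind(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L]))
    el <- el[order(el[, 1L], el[, 2L]), , drop = FALSE]
  }
  new("BinaryNetwork", nNodes = as.integer(n), edges = el)
}

#' Degree-preserving randomization by double-edge swaps
#'
#' Rewires a simple undirected graph by attempting
#' \code{ceiling(swap_factor * |E|)} double-edge swaps, skipping any swap
#' that would create a self-loop or multi-edge. The per-node degree sequence
#' is preserved exactly; graphs admitting no feasible swap (e.g. a triangle)
#' come back unchanged.
#'
#' @param g a [BinaryNetwork-class].
#' @param swap_factor attempted swaps per edge (default 10).
#' @param seed optional integer seed for reproducible rewiring.
#' @return a [BinaryNetwork-class] with the same degree sequence.
#' @export
rewireDegreePreserving <- function(g, swap_factor = 10, seed = NULL) {
  stopifnot(swap_factor > 0)
  m <- nrow(g@edges)
  if (m == 0L) return(g)
  withSeed(seed, {
    ig <- igraph::rewire(asIgraph(g),
                         igraph::keeping_degseq(loops = FALSE,
                                                niter = ceiling(swap_factor * m)))
    binaryFromIgraph(ig, g@nNodes)
  })
}

#' Edge occurrence probabilities across a cohort of binary networks
#'
#' For every unordered node pair (including pairs never observed), the
#' fraction of networks in which that edge occurs.
#'
#' @param networks non-empty list of [BinaryNetwork-class] objects sharing
#'   one node count.
#' @return numeric vector of probabilities over all \code{choose(n, 2)}
#'   pairs in ascending lexicographic pair order, with attribute
#'   \code{n_nodes}.
#' @export
edgeOccurrenceProbabilities <- function(networks) {
  if (!length(networks)) stop("empty network list")
  n <- networks[[1L]]@nNodes
  if (!all(vapply(networks, function(x) x@nNodes, integer(1)) == n))
    stop("all networks must share the same node count")
  counts <- numeric(n * (n - 1L) / 2L)
  for (net in networks) {
    e <- net@edges
    if (nrow(e))
      counts[pairIndex(e[, 1L], e[, 2L], n)] <-
        counts[pairIndex(e[, 1L], e[, 2L], n)] + 1
  }
  p <- counts / length(networks)
  attr(p, "n_nodes") <- n
  p
}

#' Shannon entropy of edge occurrence (bits)
#'
#' Sum over node pairs of the binary entropy
#' \eqn{-[p \log_2 p + (1-p) \log_2 (1-p)]} of that pair's edge occurrence
#' probability, with \eqn{0 \log 0 = 0}. This treats each pair as a Bernoulli
#' variable across the cohort; the argmax of an entropy difference is
#' invariant to the log base, and bits are used for reporting.
#'
#' @param p numeric vector of probabilities in [0, 1], as returned by
#'   [edgeOccurrenceProbabilities()].
#' @return total entropy in bits (non-negative, at most \code{length(p)}).
#' @export
occurrenceEntropy <- function(p) {
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  q <- 1 - p
  h <- numeric(length(p))
  nz <- p > 0 & p < 1
  h[nz] <- -(p[nz] * log2(p[nz]) + q[nz] * log2(q[nz]))
  sum(h)
}

#' Scan thresholds for the entropy-optimal K
#'
#' For each K on the grid, every subject's weighted network is binarized at
#' its K strongest edges and the cohort's edge-occurrence entropy is
#' computed. A null ensemble of \code{n_random} networks is built by
#' repeatedly rewiring (degree-preservingly) the binarized network of one
#' uniformly chosen subject, and its occurrence entropy is computed the same
#' way. The optimal K maximizes h_null - h_actual; ties break toward the
#' smaller K. The scan is reproducible under \code{seed}.
#'
#' @param cohort_weights list of [WeightedConnectome-class] objects (or a
#'   [ConnectomeCohort-class]).
#' @param k_grid integer vector of thresholds; defaults to all K giving mean
#'   degree in [2, 20].
#' @param n_random null-ensemble size per K (default 500).
#' @param swap_factor attempted swaps per edge during rewiring.
#' @param seed integer seed.
#' @return an [EntropyScan-class].
#' @export
scanOptimalK <- function(cohort_weights, k_grid = NULL, n_random = 500L,
                         swap_factor = 10, seed = NULL) {
  if (is(cohort_weights, "ConnectomeCohort"))
    cohort_weights <- cohort_weights@connectomes
  stopifnot(length(cohort_weights) >= 1L, n_random >= 1L)
  n <- nrow(cohort_weights[[1L]]@weights)
  if (is.null(k_grid)) k_grid <- defaultKGrid(n)
  k_grid <- sort(as.integer(k_grid))
  min_pos <- min(vapply(cohort_weights, function(x) {
    w <- x@weights; sum(w[upper.tri(w)] > 0)
  }, numeric(1)))
  if (max(k_grid) > min_pos)
    stop("k grid exceeds the positive-edge count (", min_pos,
         ") of at least one subject")
  withSeed(seed, {
    h_act <- h_nul <- numeric(length(k_grid))
    for (ki in seq_along(k_grid)) {
      k <- k_grid[ki]
      nets <- lapply(cohort_weights, binarizeTopK, k = k)
      h_act[ki] <- occurrenceEntropy(edgeOccurrenceProbabilities(nets))
      nulls <- vector("list", n_random)
      for (r in seq_len(n_random)) {
        src <- nets[[sample.int(length(nets), 1L)]]
        nulls[[r]] <- rewireDegreePreserving(src, swap_factor)
      }
      h_nul[ki] <- occurrenceEntropy(edgeOccurrenceProbabilities(nulls))
    }
    delta <- h_nul - h_act
    opt <- k_grid[which.max(delta)]  # which.max returns the first (smallest K)
    new("EntropyScan", kGrid = k_grid, hActual = h_act, hNull = h_nul,
        delta = delta, optimalK = as.integer(opt),
        nRandom = as.integer(n_random))
  })
}

#' Default threshold grid: all K giving mean degree in [2, 20]
#'
#' @param n_nodes node count.
#' @return integer vector of K values (for 83 nodes: 83..830).
#' @export
defaultKGrid <- function(n_nodes) {
  seq.int(ceiling(2 * n_nodes / 2), floor(20 * n_nodes / 2))
}
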