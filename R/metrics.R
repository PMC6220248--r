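#' Characteristic path length (CPL)
#'
#' Mean shortest-path hop count over all unordered reachable node pairs;
#' unreachable pairs are excluded from the average rather than treated as
#' infinite.
#'
#' @param g a [BinaryNetwork-class] with at least one edge.
#' @return CPL in hops (>= 1).
#' @export
characteristicPathLength <- function(g) {
  if (nrow(g@edges) == 0L) stop("CPL is undefined for an edgeless graph")
  igraph::mean_distance(asIgraph(g), directed = FALSE, unconnected = TRUE)
}

#' Global clustering coefficient (GCC)
#'
#' \code{average_local} (the default) is the mean over all nodes of the
#' local clustering coefficient — the ratio of edges among a node's
#' neighbors to the possible connections among them — with nodes of degree
#' < 2 contributing 0. \code{transitivity} is the triangle-to-connected-triple
#' ratio (3 x triangles / triples). The two differ on most graphs; both are
#' exposed because practice varies in which one a "global clustering
#' coefficient" denotes.
#'
#' @param g a [BinaryNetwork-class].
#' @param method "average_local" or "transitivity".
#' @return clustering coefficient in [0, 1] (NaN transitivity on
#'   triple-free graphs is returned as 0).
#' @export
globalClustering <- function(g, method = c("average_local", "transitivity")) {
  method <- match.arg(method)
  ig <- asIgraph(g)
  val <- if (method == "average_local")
    igraph::transitivity(ig, type = "localaverage", isolates = "zero")
  else
    igraph::transitivity(ig, type = "global")
  if (is.nan(val)) 0 else val
}

#' Betweenness centrality of every node (BET)
#'
#' Unnormalized shortest-path betweenness for an undirected graph: for node
#' v, the sum over unordered pairs s != t (both != v) of the fraction of
#' shortest s-t paths passing through v, each pair counted once.
#'
#' @param g a [BinaryNetwork-class].
#' @param normalized divide by (n-1)(n-2)/2 (off by default).
#' @return numeric vector of length \code{nNodes(g)}.
#' @export
betweennessAll <- function(g, normalized = FALSE) {
  igraph::betweenness(asIgraph(g), directed = FALSE, normalized = normalized)
}

#' Small-worldness (SMW)
#'
#' \deqn{SMW = (GCC_{act}/GCC_{rand}) / (CPL_{act}/CPL_{rand})}
#' where the "rand" terms are means over \code{n_random} degree-preserving
#' rewirings of the network itself. Values well above 1 indicate high
#' clustering with near-random path length.
#'
#' @param g a [BinaryNetwork-class].
#' @param n_random ensemble size (default 500).
#' @param gcc_method clustering variant, as in [globalClustering()].
#' @param swap_factor attempted swaps per edge during rewiring.
#' @param seed integer seed.
#' @return list with elements \code{smw} (NA with a warning when
#'   GCC_rand = 0, never silently infinite), \code{gcc_act},
#'   \code{gcc_rand}, \code{cpl_act}, \code{cpl_rand}.
#' @export
smallWorldness <- function(g, n_random = 500L,
                           gcc_method = c("average_local", "transitivity"),
                           swap_factor = 10, seed = NULL) {
  gcc_method <- match.arg(gcc_method)
  stopifnot(n_random >= 1L)
  gcc_act <- globalClustering(g, gcc_method)
  cpl_act <- characteristicPathLength(g)
  withSeed(seed, {
    gcc_r <- cpl_r <- numeric(n_random)
    for (r in seq_len(n_random)) {
      rg <- rewireDegreePreserving(g, swap_factor)
      gcc_r[r] <- globalClustering(rg, gcc_method)
      cpl_r[r] <- characteristicPathLength(rg)
    }
    gcc_rand <- mean(gcc_r)
    cpl_rand <- mean(cpl_r)
    smw <- if (gcc_rand == 0) {
      warning("GCC_rand is 0; small-worldness undefined, returning NA")
      NA_real_
    } else (gcc_act / gcc_rand) / (cpl_act / cpl_rand)
    list(smw = smw, gcc_act = gcc_act, gcc_rand = gcc_rand,
         cpl_act = cpl_act, cpl_rand = cpl_rand)
  })
}

#' Graph measures for a cohort of binarized networks
#'
#' Computes CPL, GCC, SMW and per-node betweenness for each subject and
#' returns them as a SummarizedExperiment: assay \code{"betweenness"}
#' (regions x subjects), rowData the region table, colData the per-subject
#' global measures.
#'
#' @param nets list of [BinaryNetwork-class] objects sharing one node count.
#' @param subject_ids character vector, one id per network.
#' @param regions region table (rowData); defaults to anonymous node names.
#' @param n_random rewiring ensemble size for SMW (default 500).
#' @param gcc_method clustering variant.
#' @param swap_factor attempted swaps per edge.
#' @param seed integer seed (per-subject sub-seeds are derived from it).
#' @return a \link[SummarizedExperiment]{SummarizedExperiment}.
#' @export
computeCohortMetrics <- function(nets, subject_ids = NULL, regions = NULL,
                                 n_random = 500L,
                                 gcc_method = c("average_local",
                                                "transitivity"),
                                 swap_factor = 10, seed = NULL) {
  gcc_method <- match.arg(gcc_method)
  n <- nets[[1L]]@nNodes
  if (!all(vapply(nets, function(x) x@nNodes, integer(1)) == n))
    stop("all networks must share the same node count")
  if (is.null(subject_ids))
    subject_ids <- sprintf("S%03d", seq_along(nets))
  if (is.null(regions))
    regions <- regionTable(sprintf("node_%02d", seq_len(n)),
                           rep("none", n))
  seeds <- if (is.null(seed)) rep(list(NULL), length(nets))
           else as.list(deriveSeeds(seed, length(nets)))
  bet <- matrix(0, nrow = n, ncol = length(nets),
                dimnames = list(regions$region_name, subject_ids))
  cpl <- gcc <- smw <- numeric(length(nets))
  for (s in seq_along(nets)) {
    g <- nets[[s]]
    bet[, s] <- betweennessAll(g)
    sw <- smallWorldness(g, n_random = n_random, gcc_method = gcc_method,
                         swap_factor = swap_factor, seed = seeds[[s]])
    cpl[s] <- sw$cpl_act
    gcc[s] <- sw$gcc_act
    smw[s] <- sw$smw
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(betweenness = bet),
    rowData = S4Vectors::DataFrame(regions),
    colData = S4Vectors::DataFrame(
      subject_id = subject_ids, cpl = cpl, gcc = gcc, smw = smw,
      gcc_method = gcc_method, n_random_used = as.integer(n_random),
      row.names = subject_ids)
  )
}
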