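# Brute-force graph oracles, independent of igraph, for graphs small enough
# to enumerate exhaustively.

adjFromNet <- function(net) {
  n <- nNodes(net)
  a <- matrix(0L, n, n)
  e <- edgeMatrix(net)
  if (nrow(e)) {
    a[e] <- 1L
    a[e[, 2:1, drop = FALSE]] <- 1L
  }
  a
}

# single-source BFS hop distances (-1 = unreachable)
oracleBfs <- function(adj, s) {
  n <- nrow(adj)
  d <- rep(-1L, n)
  d[s] <- 0L
  frontier <- s
  while (length(frontier)) {
    nxt <- integer()
    for (v in frontier) {
      nb <- which(adj[v, ] == 1L & d < 0)
      d[nb] <- d[v] + 1L
      nxt <- c(nxt, nb)
    }
    frontier <- unique(nxt)
  }
  d
}

oracleCPL <- function(net) {
  adj <- adjFromNet(net)
  n <- nrow(adj)
  tot <- 0; cnt <- 0
  for (s in seq_len(n - 1)) {
    d <- oracleBfs(adj, s)
    for (t in (s + 1):n) if (d[t] > 0) { tot <- tot + d[t]; cnt <- cnt + 1 }
  }
  if (cnt == 0) stop("no reachable pairs")
  tot / cnt
}

# all shortest s-t paths by exhaustive simple-path enumeration
oracleShortestPaths <- function(adj, s, t) {
  n <- nrow(adj)
  dist <- oracleBfs(adj, s)[t]
  if (dist < 0) return(list())
  paths <- list()
  recurse <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      if (length(path) - 1L == dist) paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    if (length(path) - 1L >= dist) return(invisible())
    for (w in which(adj[v, ] == 1L)) if (!(w %in% path)) recurse(c(path, w))
  }
  recurse(s)
  paths
}

oracleBetweenness <- function(net) {
  adj <- adjFromNet(net)
  n <- nrow(adj)
  bet <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- oracleShortestPaths(adj, s, t)
    if (!length(paths)) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      thru <- sum(vapply(paths, function(p) v %in% p, logical(1)))
      bet[v] <- bet[v] + thru / length(paths)
    }
  }
  bet
}

oracleAvgLocalClustering <- function(net) {
  adj <- adjFromNet(net)
  n <- nrow(adj)
  cc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(adj[v, ] == 1L)
    k <- length(nb)
    if (k < 2) { cc[v] <- 0; next }
    links <- sum(adj[nb, nb]) / 2
    cc[v] <- links / choose(k, 2)
  }
  mean(cc)
}

oracleTransitivity <- function(net) {
  adj <- adjFromNet(net)
  n <- nrow(adj)
  tri <- 0; triples <- 0
  for (v in seq_len(n)) {
    nb <- which(adj[v, ] == 1L)
    k <- length(nb)
    triples <- triples + choose(k, 2)
    if (k >= 2) tri <- tri + sum(adj[nb, nb]) / 2  # triangles centred at v
  }
  if (triples == 0) return(0)
  tri / triples  # each triangle counted at its 3 centres = 3*T / triples
}

# random simple graph as a BinaryNetwork (guaranteed >= 1 edge)
randomBinaryNet <- function(n, p = 0.4) {
  repeat {
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    keep <- runif(nrow(pairs)) < p
    if (any(keep)) break
  }
  e <- pairs[keep, , drop = FALSE]
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  storage.mode(e) <- "integer"
  new("BinaryNetwork", nNodes = as.integer(n), edges = e)
}

# random valid weighted connectome over a given region table
randomConnectome <- function(regions, density = 0.5, id = "rand") {
  n <- nrow(regions)
  w <- matrix(0, n, n)
  up <- which(upper.tri(w))
  on <- up[runif(length(up)) < density]
  w[on] <- round(runif(length(on), 0.1, 10), 6)
  w <- w + t(w)
  dimnames(w) <- list(regions$region_name, regions$region_name)
  con <- new("WeightedConnectome", subjectId = id, weights = w,
             regions = regions, weightUnit = "synthetic")
  validObject(con)
  con
}

binaryFromIgraphTest <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  storage.mode(el) <- "integer"
  el <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  new("BinaryNetwork", nNodes = as.integer(igraph::vcount(g)), edges = el)
}

smallRegions <- function(n, prefix = "R") {
  regionTable(paste0(prefix, seq_len(n)), rep("none", n))
}
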