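test_that("top-K binarization matches a brute-force sort and keeps every positive edge at full K", {
  set.seed(301)
  rt <- smallRegions(8)
  for (rep in 1:10) {
    con <- randomConnectome(rt, density = 0.6)
    w <- connectomeWeights(con)
    pos <- sum(w[upper.tri(w)] > 0)
    # no-op threshold: every positive edge survives
    all_net <- binarizeTopK(con, pos)
    expect_equal(edgeCount(all_net), pos)
    adj <- adjFromNet(all_net)
    expect_identical(adj == 1L, unname(w) > 0)

    # brute-force oracle: sort all pairs by weight, take the top k
    k <- 5L
    net <- binarizeTopK(con, k)
    pairs <- which(upper.tri(w), arr.ind = TRUE)
    ord <- order(-w[pairs], pairs[, 1], pairs[, 2])
    expected <- pairs[ord[1:k], , drop = FALSE]
    expected <- expected[order(expected[, 1], expected[, 2]), ]
    expect_equal(unname(edgeMatrix(net)), unname(expected))
  }
  expect_error(binarizeTopK(randomConnectome(rt), 10000), "between 1 and")
})

test_that("ties at the cut break toward ascending lexicographic pairs", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 5
  w[1, 3] <- w[3, 1] <- 2
  w[2, 4] <- w[4, 2] <- 2
  w[3, 4] <- w[4, 3] <- 2
  net <- binarizeTopK(w, 2)
  expect_equal(unname(edgeMatrix(net)), rbind(c(1L, 2L), c(1L, 3L)))
})

test_that("binarization is monotone in K when no tie spans the cut", {
  set.seed(333)
  rt <- smallRegions(9)
  con <- randomConnectome(rt, density = 0.7)  # continuous weights: no ties
  for (k in 1:10) {
    a <- edgeMatrix(binarizeTopK(con, k))
    b <- edgeMatrix(binarizeTopK(con, k + 1L))
    expect_true(all(apply(a, 1, paste, collapse = "-") %in%
                    apply(b, 1, paste, collapse = "-")))
  }
})

test_that("degree-preserving rewiring conserves the degree sequence and mixes the edge set", {
  tri <- new("BinaryNetwork", nNodes = 3L,
             edges = rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L)))
  expect_identical(edgeMatrix(rewireDegreePreserving(tri, seed = 1)),
                   edgeMatrix(tri))

  deg <- function(net) tabulate(edgeMatrix(net), nbins = nNodes(net))
  jaccard <- function(a, b) {
    ka <- apply(edgeMatrix(a), 1, paste, collapse = "-")
    kb <- apply(edgeMatrix(b), 1, paste, collapse = "-")
    length(intersect(ka, kb)) / length(union(ka, kb))
  }
  set.seed(404)
  mixed <- logical(100)
  for (r in 1:100) {
    g <- randomBinaryNet(20, p = 40 / choose(20, 2))
    rg <- rewireDegreePreserving(g)
    expect_identical(deg(rg), deg(g))
    mixed[r] <- jaccard(g, rg) < 0.8
  }
  expect_gte(mean(mixed), 0.95)
})

test_that("edge occurrence probabilities agree with a direct counting loop", {
  set.seed(55)
  nets <- replicate(5, randomBinaryNet(7), simplify = FALSE)
  p <- edgeOccurrenceProbabilities(nets)
  pairs <- t(combn(7, 2))
  manual <- apply(pairs, 1, function(pr) {
    mean(vapply(nets, function(net) {
      any(edgeMatrix(net)[, 1] == pr[1] & edgeMatrix(net)[, 2] == pr[2])
    }, logical(1)))
  })
  expect_equal(as.vector(p), manual)

  single <- edgeOccurrenceProbabilities(nets[1])
  expect_true(all(single %in% c(0, 1)))
  two <- edgeOccurrenceProbabilities(list(
    new("BinaryNetwork", nNodes = 3L, edges = rbind(c(1L, 2L))),
    new("BinaryNetwork", nNodes = 3L, edges = rbind(c(1L, 3L)))))
  expect_equal(as.vector(two), c(0.5, 0.5, 0))
})

test_that("occurrence entropy follows the per-pair Bernoulli formula", {
  expect_equal(occurrenceEntropy(c(0, 1, 0, 1)), 0)
  expect_equal(occurrenceEntropy(c(0.5, 0, 0)), 1)
  set.seed(66)
  p <- runif(30)
  manual <- sum(vapply(p, function(q) {
    if (q == 0 || q == 1) 0 else -(q * log2(q) + (1 - q) * log2(1 - q))
  }, numeric(1)))
  expect_equal(occurrenceEntropy(p), manual)
  expect_error(occurrenceEntropy(c(0.5, 1.2)), "\\[0, 1\\]")
  # bounded by one bit per pair
  expect_lte(occurrenceEntropy(p), length(p))
})

test_that("the K scan separates actual and null ensembles and is seed-reproducible", {
  set.seed(77)
  rt <- smallRegions(12)
  con <- randomConnectome(rt, density = 0.8)
  clones <- lapply(1:6, function(i) {
    new("WeightedConnectome", subjectId = paste0("s", i),
        weights = connectomeWeights(con), regions = rt)
  })
  scan <- scanOptimalK(clones, k_grid = c(5L, 10L, 15L), n_random = 30,
                       seed = 9)
  # identical cohort: zero actual entropy at every K
  expect_equal(scan@hActual, rep(0, 3))
  expect_equal(optimalK(scan), scan@kGrid[which.max(scan@hNull)])

  scan2 <- scanOptimalK(clones, k_grid = c(5L, 10L, 15L), n_random = 30,
                        seed = 9)
  expect_identical(entropyTable(scan), entropyTable(scan2))

  # null-ensemble size cannot affect the actual entropy
  set.seed(78)
  mixed <- lapply(1:5, function(i) randomConnectome(rt, id = paste0("m", i)))
  s1 <- scanOptimalK(mixed, k_grid = c(5L, 10L), n_random = 1, seed = 4)
  s500 <- scanOptimalK(mixed, k_grid = c(5L, 10L), n_random = 40, seed = 4)
  expect_identical(s1@hActual, s500@hActual)
})

test_that("the scan recovers a planted backbone size (Monte-Carlo)", {
  hits <- logical(20)
  for (r in seq_len(20)) {
    cfg <- generatorConfig(n_subjects = 15, n_nodes = 30, backbone_edges = 60,
                           n_noise_edges = 60, effect_nodes = 2L, gamma = 0,
                           beta_trait = 0, seed = 1000 + r)
    gen <- generateCohort(cfg)
    scan <- scanOptimalK(gen$cohort, k_grid = seq(20L, 120L, 5L),
                         n_random = 100, seed = 2000 + r)
    hits[r] <- abs(optimalK(scan) - 60) <= 15
  }
  expect_gte(mean(hits), 0.8)
})
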