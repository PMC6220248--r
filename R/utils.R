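# Evaluate expr under a temporary RNG seed, restoring the caller's RNG state.
# seed = NULL leaves the RNG untouched.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic per-stage sub-seeds from one master seed, so changing the
# draw count in one stage does not perturb another stage's stream.
deriveSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Canonical linear index of unordered pairs (i < j), ascending lexicographic.
pairIndex <- function(i, j, n) {
  # position of (i, j) in the sequence (1,2),(1,3),...,(1,n),(2,3),...
  (i - 1) * n - (i - 1) * i / 2 + (j - i)
}

# All unordered pairs in canonical order as an m x 2 integer matrix.
allPairs <- function(n) {
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L, from = 2L:n)
  cbind(i = i, j = j)
}

newConnectome <- function(subject_id, weights, regions,
                          weight_unit = "unspecified") {
  dimnames(weights) <- list(regions$region_name, regions$region_name)
  new("WeightedConnectome", subjectId = as.character(subject_id),
      weights = weights, regions = regions, weightUnit = weight_unit)
}
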