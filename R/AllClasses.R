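#' @import methods
#' @importFrom stats sd var coef lm pt pf quantile rnorm runif rbinom rlnorm
#'   cooks.distance setNames predict qnorm cor
#' @importFrom utils read.csv write.csv head
NULL

SYMMETRY_TOL <- 1e-9

#' WeightedConnectome: one subject's weighted structural network
#'
#' Holds an N x N non-negative symmetric connectivity matrix (zero diagonal)
#' together with the region table defining node order, plus a free-text
#' weight-unit tag (connectivity strength units are not imposed: streamline
#' count, density and other tractography-derived weights are all accepted
#' as given).
#'
#' @slot subjectId single character subject identifier.
#' @slot weights numeric N x N matrix; symmetric within 1e-9, diagonal 0,
#'   all entries >= 0.
#' @slot regions data.frame region table (see [regionTable()]).
#' @slot weightUnit free-text description of the edge-weight units.
#' @export
setClass("WeightedConnectome",
  representation(
    subjectId = "character",
    weights = "matrix",
    regions = "data.frame",
    weightUnit = "character"
  ),
  prototype(weightUnit = "unspecified")
)

setValidity("WeightedConnectome", function(object) {
  msg <- character()
  w <- object@weights
  if (length(object@subjectId) != 1L || is.na(object@subjectId))
    msg <- c(msg, "subjectId must be a single non-NA string")
  if (!is.numeric(w) || nrow(w) != ncol(w))
    msg <- c(msg, "weights must be a square numeric matrix")
  else {
    if (nrow(w) != nrow(object@regions))
      msg <- c(msg, "weights dimension must equal the number of regions")
    if (any(!is.finite(w)))
      msg <- c(msg, "weights must be finite")
    else {
      if (max(abs(w - t(w))) > SYMMETRY_TOL)
        msg <- c(msg, sprintf("weights asymmetric beyond tolerance %g",
                              SYMMETRY_TOL))
      if (any(diag(w) != 0))
        msg <- c(msg, "diagonal must be exactly zero")
      if (any(w < 0))
        msg <- c(msg, "weights must be non-negative")
    }
  }
  rt_msg <- checkRegionTable(object@regions)
  if (!isTRUE(rt_msg)) msg <- c(msg, rt_msg)
  if (length(msg)) msg else TRUE
})

#' ConnectomeCohort: a subject-indexed collection of connectomes
#'
#' Bundles one [WeightedConnectome-class] per subject with a covariate table
#' (subject_id, age in years, sex coded "male"/"female", trait_score) and an
#' optional integer matrix of item-level questionnaire responses (subjects in
#' rows, items in columns, categories 0..4).
#'
#' @slot connectomes named list of [WeightedConnectome-class] objects.
#' @slot covariates data.frame with columns subject_id, age, sex, trait_score.
#' @slot items integer matrix of item responses or a 0-row matrix when absent.
#' @export
setClass("ConnectomeCohort",
  representation(
    connectomes = "list",
    covariates = "data.frame",
    items = "matrix"
  ),
  prototype(items = matrix(integer(), nrow = 0, ncol = 0))
)

setValidity("ConnectomeCohort", function(object) {
  msg <- character()
  cov <- object@covariates
  need <- c("subject_id", "age", "sex", "trait_score")
  if (!all(need %in% names(cov)))
    return(paste("covariates must contain columns:",
                 paste(need, collapse = ", ")))
  ids <- vapply(object@connectomes, function(x) x@subjectId, character(1))
  if (anyDuplicated(ids))
    msg <- c(msg, "duplicate subject_id among connectomes")
  if (anyDuplicated(cov$subject_id))
    msg <- c(msg, "duplicate subject_id in covariates")
  if (!identical(unname(ids), as.character(cov$subject_id)))
    msg <- c(msg, "subject ids of connectomes and covariates must match in order")
  if (anyNA(cov[need]))
    msg <- c(msg, "missing covariate values are not allowed")
  if (!all(cov$sex %in% c("male", "female")))
    msg <- c(msg, "sex must be 'male' or 'female'")
  if (length(object@connectomes) > 1L) {
    ref <- object@connectomes[[1L]]@regions
    same <- vapply(object@connectomes,
                   function(x) identical(x@regions, ref), logical(1))
    if (!all(same))
      msg <- c(msg, "all connectomes must share one region table")
  }
  if (nrow(object@items) > 0L && nrow(object@items) != nrow(cov))
    msg <- c(msg, "item matrix must have one row per subject")
  if (length(msg)) msg else TRUE
})

#' BinaryNetwork: an undirected simple graph from top-K thresholding
#'
#' @slot nNodes integer node count.
#' @slot edges integer m x 2 matrix of node pairs (1-based, each row i < j,
#'   rows in ascending lexicographic order, no duplicates).
#' @export
setClass("BinaryNetwork",
  representation(nNodes = "integer", edges = "matrix")
)

setValidity("BinaryNetwork", function(object) {
  e <- object@edges
  n <- object@nNodes
  msg <- character()
  if (length(n) != 1L || is.na(n) || n < 1L)
    return("nNodes must be a positive integer")
  if (ncol(e) != 2L) return("edges must have two columns")
  if (nrow(e)) {
    if (any(e < 1L) || any(e > n)) msg <- c(msg, "edge endpoint out of range")
    if (any(e[, 1L] >= e[, 2L])) msg <- c(msg, "edges must satisfy i < j (no self-loops)")
    key <- (e[, 1L] - 1) * n + e[, 2L]
    if (anyDuplicated(key)) msg <- c(msg, "duplicate edges are not allowed")
    if (is.unsorted(key)) msg <- c(msg, "edges must be in ascending lexicographic order")
  }
  if (length(msg)) msg else TRUE
})

#' EntropyScan: per-K entropy profile and the selected optimal K
#'
#' @slot kGrid integer thresholds scanned.
#' @slot hActual Shannon entropy (bits) of edge occurrence in the observed
#'   cohort, per K.
#' @slot hNull entropy (bits) of the degree-preserving null ensemble, per K.
#' @slot delta hNull - hActual per K.
#' @slot optimalK the K maximizing delta (smallest such K on ties).
#' @slot nRandom size of the null ensemble per K.
#' @export
setClass("EntropyScan",
  representation(
    kGrid = "integer",
    hActual = "numeric",
    hNull = "numeric",
    delta = "numeric",
    optimalK = "integer",
    nRandom = "integer"
  )
)

setValidity("EntropyScan", function(object) {
  msg <- character()
  k <- length(object@kGrid)
  if (length(object@hActual) != k || length(object@hNull) != k ||
      length(object@delta) != k)
    msg <- c(msg, "entropy vectors must match the K grid length")
  if (!(object@optimalK %in% object@kGrid))
    msg <- c(msg, "optimalK must lie on the K grid")
  if (any(object@hActual < 0) || any(object@hNull < 0))
    msg <- c(msg, "entropies must be non-negative")
  if (length(msg)) msg else TRUE
})

#' AssociationModel: the LASSO-selected, outlier-screened OLS fit
#'
#' Coefficient rows follow the conventional report order: standardized beta,
#' its standard error, t value and two-sided p, plus a significance flag at
#' the configured alpha level.
#'
#' @slot coefficients data.frame with columns term, beta, se, t, p,
#'   significant.
#' @slot selected character vector of LASSO-selected predictor names.
#' @slot removedSubjects subject ids dropped by the Cook's-distance rule.
#' @slot fit list of fit statistics (sigma, df_residual, r_squared,
#'   adj_r_squared, f_statistic, f_df1, f_df2, model_p).
#' @slot provenance list recording seed, penalty, folds, alpha level,
#'   Cook's multiplier and stage bookkeeping.
#' @export
setClass("AssociationModel",
  representation(
    coefficients = "data.frame",
    selected = "character",
    removedSubjects = "character",
    fit = "list",
    provenance = "list"
  )
)

setValidity("AssociationModel", function(object) {
  cf <- object@coefficients
  need <- c("term", "beta", "se", "t", "p", "significant")
  if (!all(need %in% names(cf)))
    return(paste("coefficients must contain columns:",
                 paste(need, collapse = ", ")))
  alpha <- object@provenance$alpha_level
  if (!is.null(alpha) && nrow(cf) &&
      !identical(cf$significant, cf$p < alpha))
    return("significance flags must equal p < alpha_level")
  TRUE
})
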