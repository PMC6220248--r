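#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname accessors
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname accessors
#' @export
setGeneric("connectomeWeights", function(x) standardGeneric("connectomeWeights"))

#' @rdname accessors
#' @export
setGeneric("regions", function(x) standardGeneric("regions"))

#' @rdname accessors
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname accessors
#' @export
setGeneric("edgeMatrix", function(x) standardGeneric("edgeMatrix"))

#' @rdname accessors
#' @export
setGeneric("edgeCount", function(x) standardGeneric("edgeCount"))

#' @rdname accessors
#' @export
setGeneric("covariates", function(x) standardGeneric("covariates"))

#' @rdname accessors
#' @export
setGeneric("itemResponses", function(x) standardGeneric("itemResponses"))

#' @rdname accessors
#' @export
setGeneric("connectomes", function(x) standardGeneric("connectomes"))

#' @rdname accessors
#' @export
setGeneric("optimalK", function(x) standardGeneric("optimalK"))

#' @rdname accessors
#' @export
setGeneric("entropyTable", function(x) standardGeneric("entropyTable"))

#' @rdname accessors
#' @export
setGeneric("coefficientTable", function(x) standardGeneric("coefficientTable"))

#' @rdname accessors
#' @export
setGeneric("selectedPredictors", function(x) standardGeneric("selectedPredictors"))

#' @rdname accessors
#' @export
setGeneric("removedSubjects", function(x) standardGeneric("removedSubjects"))

#' @rdname accessors
#' @export
setGeneric("fitStatistics", function(x) standardGeneric("fitStatistics"))

#' Convert a package graph object to an igraph graph
#'
#' @param x object to convert.
#' @return an igraph undirected simple graph with the same node count.
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))

#' Accessors for connectropy classes
#'
#' Small read-only accessors for the S4 containers: subject identifiers,
#' weight matrices, region tables, node/edge structure of binarized networks,
#' cohort covariates and item responses, the entropy-scan profile, and the
#' association model's coefficient table, selection and fit statistics.
#'
#' @param x a connectropy object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("subjectId", "WeightedConnectome", function(x) x@subjectId)

#' @rdname accessors
#' @export
setMethod("connectomeWeights", "WeightedConnectome", function(x) x@weights)

#' @rdname accessors
#' @export
setMethod("regions", "WeightedConnectome", function(x) x@regions)

#' @rdname accessors
#' @export
setMethod("nNodes", "WeightedConnectome", function(x) nrow(x@weights))

#' @rdname accessors
#' @export
setMethod("subjectIds", "ConnectomeCohort",
          function(x) as.character(x@covariates$subject_id))

#' @rdname accessors
#' @export
setMethod("connectomes", "ConnectomeCohort", function(x) x@connectomes)

#' @rdname accessors
#' @export
setMethod("covariates", "ConnectomeCohort", function(x) x@covariates)

#' @rdname accessors
#' @export
setMethod("itemResponses", "ConnectomeCohort", function(x) x@items)

#' @rdname accessors
#' @export
setMethod("regions", "ConnectomeCohort",
          function(x) x@connectomes[[1L]]@regions)

#' @rdname accessors
#' @export
setMethod("nNodes", "BinaryNetwork", function(x) x@nNodes)

#' @rdname accessors
#' @export
setMethod("edgeMatrix", "BinaryNetwork", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("edgeCount", "BinaryNetwork", function(x) nrow(x@edges))

#' @rdname accessors
#' @export
setMethod("optimalK", "EntropyScan", function(x) x@optimalK)

#' @rdname accessors
#' @export
setMethod("entropyTable", "EntropyScan", function(x)
  data.frame(k = x@kGrid, h_actual = x@hActual, h_null = x@hNull,
             delta = x@delta))

#' @rdname accessors
#' @export
setMethod("coefficientTable", "AssociationModel", function(x) x@coefficients)

#' @rdname accessors
#' @export
setMethod("selectedPredictors", "AssociationModel", function(x) x@selected)

#' @rdname accessors
#' @export
setMethod("removedSubjects", "AssociationModel", function(x) x@removedSubjects)

#' @rdname accessors
#' @export
setMethod("fitStatistics", "AssociationModel", function(x) x@fit)

setMethod("show", "WeightedConnectome", function(object) {
  w <- object@weights
  cat("WeightedConnectome '", object@subjectId, "': ",
      nrow(w), " nodes, ", sum(w[upper.tri(w)] > 0),
      " positive edges (unit: ", object@weightUnit, ")\n", sep = "")
})

setMethod("show", "ConnectomeCohort", function(object) {
  cat("ConnectomeCohort: ", length(object@connectomes), " subjects, ",
      nrow(object@connectomes[[1L]]@weights), " nodes",
      if (nrow(object@items)) sprintf(", %d trait items", ncol(object@items)),
      "\n", sep = "")
})

setMethod("show", "BinaryNetwork", function(object) {
  cat("BinaryNetwork: ", object@nNodes, " nodes, ",
      nrow(object@edges), " edges\n", sep = "")
})

setMethod("show", "EntropyScan", function(object) {
  cat("EntropyScan over ", length(object@kGrid), " thresholds (nRandom = ",
      object@nRandom, ")\n  optimal K = ", object@optimalK,
      " (delta = ", format(max(object@delta), digits = 4), " bits)\n",
      sep = "")
})

setMethod("show", "AssociationModel", function(object) {
  cf <- object@coefficients
  cat("AssociationModel: ", nrow(cf), " coefficients, ",
      sum(cf$significant), " significant at p < ",
      object@provenance$alpha_level, "\n", sep = "")
  cat("  removed subjects:",
      if (length(object@removedSubjects))
        paste(object@removedSubjects, collapse = ", ") else "none", "\n")
  if (!is.null(object@fit$adj_r_squared))
    cat(sprintf("  adjusted R-squared %.3f; F = %.2f on %d and %d df\n",
                object@fit$adj_r_squared, object@fit$f_statistic,
                object@fit$f_df1, object@fit$f_df2))
})
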