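#' Read a weighted connectivity matrix
#'
#' Supported formats: \describe{
#'   \item{matrix-csv}{an N x N comma-separated numeric grid, with an optional
#'     header row and first column of region names;}
#'   \item{edge-list}{a 3-column TSV with header (source_name, target_name,
#'     weight); pairs absent from the file get weight 0;}
#'   \item{graphml}{GraphML with node attribute \code{region_name} and edge
#'     attribute \code{weight}.}
#' }
#' Files carrying region names are reconciled against \code{regions} by name;
#' a bare numeric grid is taken in region-table order. Invariant violations
#' (asymmetry beyond 1e-9, negative weights, non-zero diagonal, unknown
#' region names, shape mismatch) are errors, never silently repaired.
#'
#' @param path file path.
#' @param format one of "matrix-csv", "edge-list", "graphml".
#' @param regions region table (see [regionTable()]).
#' @param subject_id subject identifier for the returned object.
#' @return a [WeightedConnectome-class].
#' @export
readWeightMatrix <- function(path, format = c("matrix-csv", "edge-list",
                                              "graphml"),
                             regions, subject_id = basename(path)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  n <- nrow(regions)
  w <- switch(format,
    "matrix-csv" = readMatrixCsv(path, regions),
    "edge-list" = readEdgeList(path, regions),
    "graphml" = readGraphml(path, regions)
  )
  if (!identical(dim(w), c(n, n)))
    stop("matrix shape ", nrow(w), "x", ncol(w),
         " does not match region table of size ", n)
  if (max(abs(w - t(w))) > SYMMETRY_TOL)
    stop("matrix is asymmetric beyond tolerance; refusing to symmetrize")
  if (any(diag(w) != 0)) stop("diagonal entries must be zero")
  if (any(w < 0)) stop("negative weights are not allowed")
  newConnectome(subject_id, w, regions)
}

readMatrixCsv <- function(path, regions) {
  first <- readLines(path, n = 1L)
  toks <- strsplit(first, ",", fixed = TRUE)[[1L]]
  named <- anyNA(suppressWarnings(as.numeric(toks[toks != ""])))
  if (named) {
    df <- read.csv(path, header = TRUE, row.names = 1L,
                   check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df)
    if (!setequal(rownames(m), regions$region_name) ||
        !setequal(colnames(m), regions$region_name))
      stop("region names in file do not match the region table")
    m <- m[regions$region_name, regions$region_name, drop = FALSE]
  } else {
    m <- as.matrix(read.csv(path, header = FALSE))
    dimnames(m) <- NULL
  }
  storage.mode(m) <- "double"
  m
}

readEdgeList <- function(path, regions) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L)
    stop("edge list must have 3 columns: source_name, target_name, weight")
  n <- nrow(regions)
  idx <- function(nm) {
    m <- match(nm, regions$region_name)
    if (anyNA(m))
      stop("unknown region name(s) in edge list: ",
           paste(unique(nm[is.na(m)]), collapse = ", "))
    m
  }
  i <- idx(as.character(df[[1L]]))
  j <- idx(as.character(df[[2L]]))
  wt <- as.numeric(df[[3L]])
  if (any(i == j)) stop("self-loops (non-zero diagonal) are not allowed")
  w <- matrix(0, n, n)
  # duplicate unordered pairs with conflicting weights are asymmetry
  lo <- pmin(i, j); hi <- pmax(i, j)
  key <- pairIndex(lo, hi, n)
  if (anyDuplicated(key)) {
    agg <- tapply(wt, key, function(v) diff(range(v)))
    if (any(agg > SYMMETRY_TOL))
      stop("conflicting duplicate entries for a node pair (asymmetric input)")
  }
  w[cbind(lo, hi)] <- wt
  w[cbind(hi, lo)] <- wt
  w
}

readGraphml <- function(path, regions) {
  g <- igraph::read_graph(path, format = "graphml")
  nm <- igraph::vertex_attr(g, "region_name")
  if (is.null(nm)) stop("graphml file lacks the 'region_name' node attribute")
  m <- match(nm, regions$region_name)
  if (anyNA(m)) stop("unknown region name(s) in graphml: ",
                     paste(nm[is.na(m)], collapse = ", "))
  n <- nrow(regions)
  if (length(nm) != n) stop("graphml node count does not match region table")
  el <- igraph::as_edgelist(g, names = FALSE)
  wt <- igraph::edge_attr(g, "weight")
  if (is.null(wt)) stop("graphml file lacks the 'weight' edge attribute")
  w <- matrix(0, n, n)
  i <- m[el[, 1L]]; j <- m[el[, 2L]]
  w[cbind(i, j)] <- wt
  w[cbind(j, i)] <- wt
  w
}

#' Write a weighted connectome to disk
#'
#' @param x a [WeightedConnectome-class].
#' @param path output file path.
#' @param format one of "matrix-csv", "edge-list", "graphml".
#' @return invisibly, \code{path}.
#' @export
writeWeightMatrix <- function(x, path, format = c("matrix-csv", "edge-list",
                                                  "graphml")) {
  format <- match.arg(format)
  w <- x@weights
  nm <- x@regions$region_name
  if (format == "matrix-csv") {
    # region row/col names make the files self-describing
    body <- matrix(format(w, trim = TRUE, digits = 17), nrow(w))
    lines <- c(paste(c("region", nm), collapse = ","),
               apply(cbind(nm, body), 1L, paste, collapse = ","))
    writeLines(lines, path)
  } else if (format == "edge-list") {
    up <- which(upper.tri(w) & w != 0, arr.ind = TRUE)
    df <- data.frame(source_name = nm[up[, 1L]], target_name = nm[up[, 2L]],
                     weight = format(w[up], digits = 17))
    writeLines(c("source_name\ttarget_name\tweight",
                 if (nrow(df)) paste(df[[1L]], df[[2L]], df[[3L]], sep = "\t")),
               path)
  } else {
    up <- which(upper.tri(w) & w != 0, arr.ind = TRUE)
    g <- igraph::make_empty_graph(n = nrow(w), directed = FALSE)
    g <- igraph::set_vertex_attr(g, "region_name", value = nm)
    if (nrow(up))
      g <- igraph::add_edges(g, t(up), weight = w[up])
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a cohort from a manifest CSV
#'
#' The manifest has columns subject_id, matrix_path, age, sex, trait_score,
#' plus optional item response columns item_1..item_k. Matrix paths are
#' resolved relative to the manifest's directory unless absolute.
#'
#' @param manifest_path path to the manifest CSV.
#' @param regions region table shared by all subjects;
#'   [defaultRegionTable()] by default.
#' @param format matrix file format, as in [readWeightMatrix()].
#' @return a [ConnectomeCohort-class].
#' @export
readCohort <- function(manifest_path, regions = defaultRegionTable(),
                       format = "matrix-csv") {
  mf <- read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("subject_id", "matrix_path", "age", "sex", "trait_score")
  if (!all(need %in% names(mf)))
    stop("manifest must contain columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(mf$subject_id))
    stop("duplicate subject_id in manifest")
  if (anyNA(mf[need])) stop("missing covariate values in manifest")
  base <- dirname(manifest_path)
  cons <- lapply(seq_len(nrow(mf)), function(r) {
    p <- mf$matrix_path[r]
    if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(base, p)
    readWeightMatrix(p, format = format, regions = regions,
                     subject_id = mf$subject_id[r])
  })
  names(cons) <- mf$subject_id
  item_cols <- grep("^item_[0-9]+$", names(mf), value = TRUE)
  items <- if (length(item_cols)) {
    item_cols <- item_cols[order(as.integer(sub("item_", "", item_cols)))]
    as.matrix(mf[item_cols])
  } else matrix(integer(), 0, 0)
  new("ConnectomeCohort",
      connectomes = cons,
      covariates = data.frame(subject_id = as.character(mf$subject_id),
                              age = mf$age, sex = mf$sex,
                              trait_score = mf$trait_score,
                              stringsAsFactors = FALSE),
      items = items)
}

#' Write a cohort (matrices + manifest) to a directory
#'
#' @param cohort a [ConnectomeCohort-class].
#' @param out_dir output directory (created if absent).
#' @param format matrix file format.
#' @return invisibly, the manifest path.
#' @export
writeCohort <- function(cohort, out_dir, format = "matrix-csv") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ext <- c("matrix-csv" = "csv", "edge-list" = "tsv", "graphml" = "graphml")
  cov <- cohort@covariates
  paths <- character(nrow(cov))
  for (r in seq_len(nrow(cov))) {
    paths[r] <- paste0(cov$subject_id[r], ".", ext[[format]])
    writeWeightMatrix(cohort@connectomes[[r]],
                      file.path(out_dir, paths[r]), format = format)
  }
  mf <- data.frame(subject_id = cov$subject_id, matrix_path = paths,
                   age = cov$age, sex = cov$sex,
                   trait_score = cov$trait_score)
  if (nrow(cohort@items)) {
    it <- as.data.frame(cohort@items)
    colnames(it) <- paste0("item_", seq_len(ncol(it)))
    mf <- cbind(mf, it)
  }
  manifest <- file.path(out_dir, "manifest.csv")
  write.csv(mf, manifest, row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Write pipeline results (metrics, entropy scan, association report)
#'
#' Emits \code{metrics.csv} (one row per subject x node with the node's
#' betweenness plus the subject's global measures), \code{entropy_scan.csv}
#' (k, h_actual, h_null, delta), and the association report as
#' \code{association.csv} / \code{association.json} with coefficient rows in
#' the order: standardized beta, S.E., t value, two-sided p, significance
#' flag at the configured alpha.
#'
#' @param model an [AssociationModel-class].
#' @param scan an [EntropyScan-class] or NULL.
#' @param metrics a SummarizedExperiment from [computeCohortMetrics()] or
#'   NULL.
#' @param out_dir output directory.
#' @return invisibly, named character vector of written paths.
#' @export
writeResults <- function(model, scan = NULL, metrics = NULL, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2L) != 0L)
    stop("output directory is not writable: ", out_dir)
  paths <- c()
  if (!is.null(metrics)) {
    p <- file.path(out_dir, "metrics.csv")
    write.csv(metricsLongTable(metrics), p, row.names = FALSE)
    paths["metrics"] <- p
  }
  if (!is.null(scan)) {
    p <- file.path(out_dir, "entropy_scan.csv")
    write.csv(entropyTable(scan), p, row.names = FALSE)
    paths["entropy_scan"] <- p
  }
  cf <- model@coefficients
  p_csv <- file.path(out_dir, "association.csv")
  write.csv(cf, p_csv, row.names = FALSE)
  p_json <- file.path(out_dir, "association.json")
  jsonlite::write_json(associationReportList(model), p_json,
                       auto_unbox = TRUE, digits = NA, null = "null")
  paths[c("association_csv", "association_json")] <- c(p_csv, p_json)
  invisible(paths)
}

associationReportList <- function(model) {
  prov <- model@provenance
  prov$lm_fit <- NULL  # the fitted lm object is diagnostics, not report
  list(
    coefficients = model@coefficients,
    selected = as.list(model@selected),
    removed_subjects = as.list(model@removedSubjects),
    fit = model@fit,
    provenance = prov
  )
}

#' Re-parse a written association report into an AssociationModel
#'
#' @param path path to an \code{association.json} written by
#'   [writeResults()].
#' @return an [AssociationModel-class].
#' @export
readAssociationReport <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cf <- as.data.frame(x$coefficients)
  new("AssociationModel",
      coefficients = cf,
      selected = as.character(unlist(x$selected)),
      removedSubjects = as.character(unlist(x$removed_subjects)),
      fit = x$fit,
      provenance = x$provenance)
}

metricsLongTable <- function(se) {
  bet <- SummarizedExperiment::assay(se, "betweenness")
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  rn <- SummarizedExperiment::rowData(se)$region_name
  data.frame(
    subject_id = rep(cd$subject_id, each = nrow(bet)),
    region_name = rep(rn, times = ncol(bet)),
    betweenness = as.vector(bet),
    cpl = rep(cd$cpl, each = nrow(bet)),
    gcc = rep(cd$gcc, each = nrow(bet)),
    smw = rep(cd$smw, each = nrow(bet))
  )
}
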