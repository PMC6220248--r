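RUN_CONFIG_DEFAULTS <- list(
  seed = 1L,
  out_dir = NULL,
  manifest = NULL,          # read an existing cohort instead of simulating
  simulate = NULL,          # list of generatorConfig() overrides
  k = NULL,                 # fixed threshold; NULL means scan
  k_min = NULL, k_max = NULL, k_step = 1L,
  n_random = 500L,          # null-ensemble size (thresholding and SMW)
  swap_factor = 10,
  gcc_method = "average_local",
  cv_folds = 10L,
  cooks_multiplier = 3,
  alpha_level = 0.01,
  lasso_rule = "1se"
)

#' Validate (and default) a pipeline run configuration
#'
#' Accepts a YAML file path or a list. Unknown keys are rejected; every
#' violation is reported at once. Defaults: n_random = 500,
#' cooks_multiplier = 3, alpha_level = 0.01, gcc_method = "average_local",
#' cv_folds = 10, swap_factor = 10, lasso_rule = "1se".
#'
#' @param config path to a YAML config or a named list.
#' @return the defaulted, validated config list (class \code{"runConfig"}).
#' @export
validateRunConfig <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file does not exist: ", config)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  if (inherits(config, "runConfig")) config <- unclass(config)
  errs <- character()
  unknown <- setdiff(names(config), names(RUN_CONFIG_DEFAULTS))
  if (length(unknown))
    errs <- c(errs, paste("unknown key(s):", paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(RUN_CONFIG_DEFAULTS, config, keep.null = TRUE)
  if (!is.null(cfg$simulate)) {
    sim_unknown <- setdiff(names(cfg$simulate),
                           names(formals(generatorConfig)))
    if (length(sim_unknown))
      errs <- c(errs, paste("unknown simulate key(s):",
                            paste(sim_unknown, collapse = ", ")))
  }
  if (is.null(cfg$simulate) && is.null(cfg$manifest))
    errs <- c(errs, "either a simulate block or a manifest is required")
  num_pos <- c(n_random = cfg$n_random, swap_factor = cfg$swap_factor,
               cv_folds = cfg$cv_folds,
               cooks_multiplier = cfg$cooks_multiplier,
               alpha_level = cfg$alpha_level)
  bad <- names(num_pos)[!is.finite(num_pos) | num_pos <= 0]
  if (length(bad))
    errs <- c(errs, paste("must be positive:", paste(bad, collapse = ", ")))
  if (cfg$alpha_level >= 1) errs <- c(errs, "alpha_level must be below 1")
  if (!cfg$gcc_method %in% c("average_local", "transitivity"))
    errs <- c(errs, "gcc_method must be 'average_local' or 'transitivity'")
  if (!cfg$lasso_rule %in% c("min", "1se"))
    errs <- c(errs, "lasso_rule must be 'min' or '1se'")
  if (!is.null(cfg$k) && cfg$k < 1) errs <- c(errs, "k must be >= 1")
  if (!is.null(cfg$k_min) && !is.null(cfg$k_max) && cfg$k_min > cfg$k_max)
    errs <- c(errs, "k_min must not exceed k_max")
  if (length(errs)) stop(paste(errs, collapse = "; "))
  structure(cfg, class = c("runConfig", "list"))
}

#' Run the full pipeline: simulate/load, threshold, metrics, association
#'
#' Stages execute in order, each on a sub-seed derived from the master
#' seed so one stage's draw count cannot perturb another's. When
#' \code{out_dir} is set, every stage's artifacts are written (cohort
#' manifest + matrices, ground truth, entropy scan, metrics table,
#' association report) together with a run manifest recording the config
#' snapshot, seeds and wall-clock per stage. Precomputed stage outputs can
#' be injected through \code{precomputed} to resume a run.
#'
#' @param config a [validateRunConfig()] input (list, runConfig or YAML
#'   path).
#' @param precomputed optional named list with any of \code{cohort},
#'   \code{scan}, \code{metrics} to skip the corresponding stage.
#' @return list with \code{cohort}, \code{ground_truth}, \code{scan},
#'   \code{k}, \code{networks}, \code{metrics}, \code{model},
#'   \code{stage_seconds}, and \code{out_dir}.
#' @export
runPipeline <- function(config = list(), precomputed = list()) {
  cfg <- validateRunConfig(config)
  seeds <- deriveSeeds(cfg$seed, 4L)
  took <- c()
  tic <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    v <- force(expr)
    list(value = v, secs = proc.time()[["elapsed"]] - t0)
  }

  # stage 1: cohort
  st <- tic({
    if (!is.null(precomputed$cohort)) {
      list(cohort = precomputed$cohort, ground_truth = NULL)
    } else if (!is.null(cfg$manifest)) {
      list(cohort = readCohort(cfg$manifest), ground_truth = NULL)
    } else {
      sim <- do.call(generatorConfig,
                     utils::modifyList(cfg$simulate,
                                       list(seed = seeds[1L])))
      generateCohort(sim)
    }
  })
  cohort <- st$value$cohort
  ground_truth <- st$value$ground_truth
  took["cohort"] <- st$secs

  # stage 2: threshold selection + binarization
  st <- tic({
    if (!is.null(precomputed$scan)) {
      precomputed$scan
    } else if (is.null(cfg$k)) {
      grid <- if (!is.null(cfg$k_min) && !is.null(cfg$k_max))
        seq.int(cfg$k_min, cfg$k_max, by = cfg$k_step)
      else defaultKGrid(nNodes(cohort@connectomes[[1L]]))
      scanOptimalK(cohort, k_grid = grid, n_random = cfg$n_random,
                   swap_factor = cfg$swap_factor, seed = seeds[2L])
    } else NULL
  })
  scan <- st$value
  k <- if (!is.null(scan)) optimalK(scan) else as.integer(cfg$k)
  nets <- lapply(cohort@connectomes, binarizeTopK, k = k)
  took["threshold"] <- st$secs

  # stage 3: graph measures
  st <- tic({
    if (!is.null(precomputed$metrics)) precomputed$metrics
    else computeCohortMetrics(nets, subject_ids = subjectIds(cohort),
                              regions = regions(cohort),
                              n_random = cfg$n_random,
                              gcc_method = cfg$gcc_method,
                              swap_factor = cfg$swap_factor,
                              seed = seeds[3L])
  })
  metrics <- st$value
  took["metrics"] <- st$secs

  # stage 4: association
  st <- tic(runAssociation(metrics, cohort, cv_folds = cfg$cv_folds,
                           cooks_multiplier = cfg$cooks_multiplier,
                           alpha_level = cfg$alpha_level,
                           seed = seeds[4L], rule = cfg$lasso_rule))
  model <- st$value
  took["association"] <- st$secs

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    writeCohort(cohort, file.path(cfg$out_dir, "cohort"))
    if (!is.null(ground_truth))
      jsonlite::write_json(ground_truth,
                           file.path(cfg$out_dir, "ground_truth.json"),
                           auto_unbox = TRUE, digits = NA)
    writeResults(model, scan = scan, metrics = metrics,
                 out_dir = cfg$out_dir)
    run_manifest <- list(config = unclass(cfg)[!vapply(cfg, is.null,
                                                       logical(1))],
                         stage_seeds = seeds,
                         k_used = k,
                         stage_seconds = as.list(took),
                         package_version =
                           as.character(utils::packageVersion("connectropy")))
    jsonlite::write_json(run_manifest,
                         file.path(cfg$out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(cohort = cohort, ground_truth = ground_truth, scan = scan, k = k,
       networks = nets, metrics = metrics, model = model,
       stage_seconds = took, out_dir = cfg$out_dir)
}
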