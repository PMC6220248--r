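#' Cronbach's alpha internal-consistency coefficient
#'
#' \deqn{\alpha = \frac{k}{k-1}\left(1 - \frac{\sum_i s_i^2}{s_{total}^2}\right)}
#' where \eqn{s_i^2} is the sample variance (denominator n-1) of item i and
#' \eqn{s_{total}^2} the sample variance of the item sums.
#'
#' @param items numeric matrix, subjects in rows, k >= 2 items in columns.
#' @return alpha (errors when the total-score variance is zero).
#' @export
#' @examples
#' cronbachAlpha(cbind(c(1, 2, 3), c(1, 2, 3)))  # 1
cronbachAlpha <- function(items) {
  items <- as.matrix(items)
  k <- ncol(items)
  if (k < 2L) stop("at least 2 items are required")
  if (nrow(items) < 2L) stop("at least 2 subjects are required")
  tot <- var(rowSums(items))
  if (tot == 0) stop("total-score variance is zero; alpha undefined")
  k / (k - 1) * (1 - sum(apply(items, 2L, var)) / tot)
}

#' Assemble the standardized design matrix for trait association
#'
#' Predictor columns, in order: age, sex (male = 1, female = 0), cpl, gcc,
#' smw, then one betweenness column per region (\code{bet_<region_name>})
#' in region-table order — 88 candidates for an 83-node parcellation. All
#' predictors and the trait-score response are centered and scaled to unit
#' SD; zero-variance columns are excluded with a warning (their names are
#' kept in the standardization record).
#'
#' @param metrics SummarizedExperiment from [computeCohortMetrics()].
#' @param cohort a [ConnectomeCohort-class] covering the same subjects.
#' @return list of class \code{"designMatrix"} with elements \code{x}
#'   (standardized predictor matrix), \code{y} (standardized response),
#'   \code{subject_ids}, \code{scaling} (per-column mean and SD, including
#'   the response), and \code{dropped} (zero-variance column names).
#' @export
assembleDesign <- function(metrics, cohort) {
  cd <- as.data.frame(SummarizedExperiment::colData(metrics))
  cov <- cohort@covariates
  if (!identical(as.character(cd$subject_id), as.character(cov$subject_id)))
    stop("metrics and cohort must cover identical subjects in order")
  bet <- t(SummarizedExperiment::assay(metrics, "betweenness"))
  colnames(bet) <- paste0("bet_",
                          SummarizedExperiment::rowData(metrics)$region_name)
  raw <- cbind(
    age = cov$age,
    sex = as.numeric(cov$sex == "male"),
    cpl = cd$cpl, gcc = cd$gcc, smw = cd$smw,
    bet
  )
  y_raw <- cov$trait_score
  mu <- colMeans(raw)
  sdv <- apply(raw, 2L, sd)
  dropped <- colnames(raw)[sdv == 0]
  if (length(dropped))
    warning("excluding zero-variance predictor(s): ",
            paste(dropped, collapse = ", "))
  keep <- sdv > 0
  x <- sweep(sweep(raw[, keep, drop = FALSE], 2L, mu[keep]), 2L,
             sdv[keep], "/")
  if (sd(y_raw) == 0) stop("trait score has zero variance")
  y <- (y_raw - mean(y_raw)) / sd(y_raw)
  structure(list(
    x = x, y = y,
    subject_ids = as.character(cov$subject_id),
    scaling = data.frame(column = c(colnames(raw), ".response"),
                         mean = c(mu, mean(y_raw)),
                         sd = c(sdv, sd(y_raw))),
    dropped = dropped
  ), class = c("designMatrix", "list"))
}

#' LASSO variable selection by cross-validated penalty
#'
#' L1-penalized least squares over a log-spaced penalty path
#' (\code{glmnet}); the penalty is chosen by \code{cv_folds}-fold
#' cross-validated mean squared error (fold assignment seeded) — by default
#' the one-standard-error rule, which restores type-I control in the
#' downstream post-selection OLS; \code{rule = "min"} gives the
#' CV-minimizing penalty. Predictors with non-zero coefficients at the
#' chosen penalty are returned. Age and sex enter the penalized path like any other column;
#' the downstream OLS forces them back in if unselected.
#'
#' @param design a design list from [assembleDesign()].
#' @param cv_folds number of CV folds (default 10; must satisfy
#'   3 <= cv_folds <= n).
#' @param seed integer seed for fold assignment.
#' @param rule \code{"1se"} (default) for the one-standard-error rule or
#'   \code{"min"} for the CV-minimizing penalty.
#' @return list with \code{selected} (predictor names), \code{lambda}
#'   (chosen penalty), and \code{cvfit} (the cv.glmnet object).
#' @export
lassoSelect <- function(design, cv_folds = 10L, seed = NULL,
                        rule = c("1se", "min")) {
  rule <- match.arg(rule)
  n <- length(design$y)
  stopifnot(cv_folds >= 3L, n >= cv_folds)
  if (sd(design$y) == 0) stop("degenerate response: zero variance")
  foldid <- withSeed(seed, sample(rep_len(seq_len(cv_folds), n)))
  cvfit <- glmnet::cv.glmnet(design$x, design$y, foldid = foldid,
                             standardize = FALSE, intercept = TRUE,
                             family = "gaussian")
  lambda <- if (rule == "min") cvfit$lambda.min else cvfit$lambda.1se
  b <- coef(cvfit, s = lambda)
  nz <- rownames(b)[as.vector(b != 0)]
  list(selected = setdiff(nz, "(Intercept)"), lambda = lambda, cvfit = cvfit)
}

#' Ordinary least squares on standardized predictors
#'
#' Fits OLS with intercept on the given predictor columns (already
#' standardized), returning the coefficient table in report order
#' (standardized beta, SE, t, two-sided p from the t distribution on the
#' residual df) and the usual fit statistics (residual SE, multiple and
#' adjusted R-squared, overall F with its df and p-value).
#'
#' @param design a design list from [assembleDesign()].
#' @param predictors predictor names to include (order preserved).
#' @param subjects subject ids to fit on (default all).
#' @param alpha_level significance threshold for the flag column.
#' @return an [AssociationModel-class] (provenance carries the lm fit in
#'   \code{$lm_fit} for diagnostics).
#' @export
olsFit <- function(design, predictors, subjects = design$subject_ids,
                   alpha_level = 0.01) {
  keep <- design$subject_ids %in% subjects
  x <- design$x[keep, predictors, drop = FALSE]
  y <- design$y[keep]
  n <- sum(keep)
  p <- length(predictors)
  if (n <= p + 1L) stop("too few subjects for ", p, " predictors")
  df <- data.frame(.y = y, x, check.names = FALSE)
  fit <- lm(.y ~ ., data = df)
  if (fit$rank < p + 1L) stop("rank-deficient design: predictors are collinear")
  sm <- summary(fit)
  ct <- sm$coefficients
  terms <- rownames(ct)
  terms[terms == "(Intercept)"] <- "intercept"
  terms <- gsub("^`|`$", "", terms)
  coefs <- data.frame(
    term = terms,
    beta = ct[, 1L], se = ct[, 2L], t = ct[, 3L], p = ct[, 4L],
    significant = ct[, 4L] < alpha_level,
    row.names = NULL
  )
  fstat <- sm$fstatistic
  fitstats <- list(
    sigma = sm$sigma,
    df_residual = fit$df.residual,
    r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared,
    f_statistic = unname(fstat[1L]),
    f_df1 = unname(fstat[2L]),
    f_df2 = unname(fstat[3L]),
    model_p = unname(pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE))
  )
  stopifnot(fit$df.residual == n - p - 1L)
  new("AssociationModel",
      coefficients = coefs,
      selected = predictors,
      removedSubjects = character(),
      fit = fitstats,
      provenance = list(alpha_level = alpha_level, n_subjects = n,
                        lm_fit = fit,
                        subject_ids = design$subject_ids[keep]))
}

#' Cook's-distance outlier screen
#'
#' Computes Cook's distance for every subject in a fitted model and flags
#' those exceeding \code{multiplier} times the mean distance. Applied as a
#' single removal-and-refit pass, not iterated.
#'
#' @param model an [AssociationModel-class] from [olsFit()].
#' @param multiplier flagging threshold as a multiple of the mean Cook's
#'   distance (default 3).
#' @return character vector of flagged subject ids.
#' @export
cooksFilter <- function(model, multiplier = 3) {
  stopifnot(multiplier > 0)
  fit <- model@provenance$lm_fit
  if (is.null(fit)) stop("model carries no lm fit for diagnostics")
  d <- cooks.distance(fit)
  ids <- model@provenance$subject_ids
  ids[d > multiplier * mean(d)]
}

#' Full trait-association stage
#'
#' Pipeline order: assemble the standardized design; LASSO-select
#' predictors on all subjects; OLS with the selected predictors plus age
#' and sex forced in; one Cook's-distance screening pass
#' (\code{cooks_multiplier} times the mean); refit on the retained
#' subjects; flag coefficients at \code{p < alpha_level}. Provenance
#' (seed, penalty, folds, removed ids) is recorded on the returned model.
#'
#' @param metrics SummarizedExperiment from [computeCohortMetrics()].
#' @param cohort a [ConnectomeCohort-class].
#' @param cv_folds CV folds for the LASSO penalty.
#' @param cooks_multiplier Cook's-distance threshold multiplier.
#' @param alpha_level significance threshold (default 0.01).
#' @param seed integer seed (fold assignment).
#' @param rule penalty rule, as in [lassoSelect()].
#' @return an [AssociationModel-class].
#' @export
runAssociation <- function(metrics, cohort, cv_folds = 10L,
                           cooks_multiplier = 3, alpha_level = 0.01,
                           seed = NULL, rule = "1se") {
  design <- assembleDesign(metrics, cohort)
  sel <- lassoSelect(design, cv_folds = cv_folds, seed = seed, rule = rule)
  predictors <- union(c("age", "sex"), sel$selected)
  predictors <- predictors[predictors %in% colnames(design$x)]
  pre <- olsFit(design, predictors, alpha_level = alpha_level)
  removed <- cooksFilter(pre, multiplier = cooks_multiplier)
  final <- if (length(removed)) {
    olsFit(design, predictors,
           subjects = setdiff(design$subject_ids, removed),
           alpha_level = alpha_level)
  } else pre
  final@removedSubjects <- removed
  final@provenance <- c(final@provenance,
                        list(seed = seed, lambda = sel$lambda,
                             cv_folds = cv_folds,
                             cooks_multiplier = cooks_multiplier,
                             rule = rule,
                             lasso_selected = sel$selected,
                             dropped_columns = design$dropped))
  validObject(final)
  final
}
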