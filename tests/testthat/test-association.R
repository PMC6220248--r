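makeDesign <- function(x, y, ids = sprintf("s%03d", seq_along(y))) {
  structure(list(x = x, y = y, subject_ids = ids,
                 scaling = data.frame(), dropped = character()),
            class = c("designMatrix", "list"))
}

test_that("Cronbach's alpha matches the formula on hand-computable matrices", {
  expect_equal(cronbachAlpha(cbind(c(1, 2, 3), c(1, 2, 3))), 1)
  expect_equal(cronbachAlpha(rbind(c(1, 1), c(2, 2))), 1)
  expect_error(cronbachAlpha(rbind(c(1, 2), c(2, 1))), "variance")
  expect_error(cronbachAlpha(matrix(1:4, ncol = 1)), "2 items")

  m <- rbind(c(3, 2, 4), c(1, 1, 2), c(4, 3, 3), c(2, 4, 1))
  k <- 3
  hand <- k / (k - 1) * (1 - sum(apply(m, 2, var)) / var(rowSums(m)))
  expect_equal(cronbachAlpha(m), hand)
  # spreadsheet-style direct evaluation of the same matrix
  item_vars <- c(var(c(3, 1, 4, 2)), var(c(2, 1, 3, 4)), var(c(4, 2, 3, 1)))
  tot_var <- var(c(9, 4, 10, 7))
  expect_equal(cronbachAlpha(m), 1.5 * (1 - sum(item_vars) / tot_var))
})

test_that("the design matrix has 88 candidate predictors in report order, standardized", {
  cfg <- generatorConfig(n_subjects = 12, seed = 71)
  gen <- generateCohort(cfg)
  nets <- lapply(connectomes(gen$cohort), binarizeTopK, k = 150L)
  met <- computeCohortMetrics(nets, subjectIds(gen$cohort),
                              regions(gen$cohort), n_random = 2, seed = 5)
  design <- suppressWarnings(assembleDesign(met, gen$cohort))
  candidates <- setdiff(design$scaling$column, ".response")
  expect_length(candidates, 88L)
  expect_equal(candidates[1:5], c("age", "sex", "cpl", "gcc", "smw"))
  expect_equal(candidates[-(1:5)],
               paste0("bet_", regions(gen$cohort)$region_name))
  expect_true(all(abs(colMeans(design$x)) < 1e-12))
  expect_true(all(abs(apply(design$x, 2, sd) - 1) < 1e-12))
  expect_equal(mean(design$y), 0, tolerance = 1e-12)
  expect_equal(sd(design$y), 1, tolerance = 1e-12)
})

test_that("zero-variance columns are excluded with a warning", {
  cfg <- generatorConfig(n_subjects = 6, n_nodes = 10, backbone_edges = 15,
                         n_noise_edges = 0, effect_nodes = 2L, seed = 72)
  gen <- generateCohort(cfg)
  nets <- lapply(connectomes(gen$cohort), binarizeTopK, k = 15L)
  met <- computeCohortMetrics(nets, subjectIds(gen$cohort),
                              regions(gen$cohort), n_random = 2, seed = 6)
  # identical binarized networks per subject: bet columns are constant
  expect_warning(design <- assembleDesign(met, gen$cohort),
                 "zero-variance")
  expect_true(length(design$dropped) > 0)
  expect_false(any(design$dropped %in% colnames(design$x)))
})

test_that("LASSO shrinks fully at the top of the path and recovers planted support", {
  set.seed(801)
  n <- 100; p <- 20
  x <- scale(matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("v", 1:p))))
  y_noise <- as.vector(scale(rnorm(n)))
  d_noise <- makeDesign(x, y_noise)
  sel <- lassoSelect(d_noise, cv_folds = 5, seed = 1)
  b_top <- coef(sel$cvfit$glmnet.fit, s = max(sel$cvfit$lambda))
  expect_true(all(b_top[-1] == 0))

  # support recovery: y = 0.8 x_j + noise at SNR ~ 4, p = 88
  hits <- logical(20)
  for (r in 1:20) {
    set.seed(900 + r)
    n <- 200; p <- 88
    x <- scale(matrix(rnorm(n * p), n,
                      dimnames = list(NULL, paste0("v", 1:p))))
    y <- as.vector(scale(0.8 * x[, "v7"] + rnorm(n, sd = 0.4)))
    sel <- lassoSelect(makeDesign(x, y), cv_folds = 10, seed = r)
    hits[r] <- "v7" %in% sel$selected
  }
  expect_gte(mean(hits), 0.9)
})

test_that("LASSO solutions satisfy the KKT conditions and meet OLS at zero penalty", {
  for (r in 1:5) {
    set.seed(810 + r)
    n <- 80; p <- 12
    x <- scale(matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("v", 1:p))))
    b_true <- c(rep(1, 3), rep(0, p - 3))
    y <- as.vector(scale(x %*% b_true + rnorm(n)))
    fit <- glmnet::glmnet(x, y, standardize = FALSE, intercept = TRUE,
                          thresh = 1e-14)
    for (lam in fit$lambda[c(5, 20, length(fit$lambda))]) {
      b <- as.vector(coef(fit, s = lam, exact = TRUE, x = x, y = y,
                          standardize = FALSE, intercept = TRUE,
                          thresh = 1e-14))
      res <- y - b[1] - x %*% b[-1]
      grad <- as.vector(crossprod(x, res)) / n
      active <- b[-1] != 0
      if (any(active))
        expect_true(all(abs(grad[active] - lam * sign(b[-1][active])) < 1e-6))
      if (any(!active))
        expect_true(all(abs(grad[!active]) <= lam + 1e-6))
    }
    # zero penalty = OLS on the same columns
    b0 <- as.vector(coef(fit, s = 0, exact = TRUE, x = x, y = y,
                         standardize = FALSE, intercept = TRUE,
                         thresh = 1e-14))
    ols <- as.vector(coef(lm(y ~ x)))
    expect_equal(b0, ols, tolerance = 1e-6)
  }
})

test_that("OLS matches the normal equations and keeps residual-df bookkeeping", {
  set.seed(820)
  n <- 60; p <- 6
  x <- scale(matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("v", 1:p))))
  y <- as.vector(scale(x %*% rnorm(p) + rnorm(n)))
  model <- olsFit(makeDesign(x, y), paste0("v", 1:p))
  xa <- cbind(1, x)
  beta_ne <- solve(crossprod(xa), crossprod(xa, y))
  expect_equal(coefficientTable(model)$beta, as.vector(beta_ne),
               tolerance = 1e-10)
  expect_equal(fitStatistics(model)$df_residual, n - p - 1L)

  # a 50-subject fit on 24 predictors leaves 25 residual df
  set.seed(821)
  x50 <- scale(matrix(rnorm(50 * 24), 50,
                      dimnames = list(NULL, paste0("v", 1:24))))
  y50 <- as.vector(scale(rnorm(50)))
  m50 <- olsFit(makeDesign(x50, y50), paste0("v", 1:24))
  expect_equal(fitStatistics(m50)$df_residual, 25L)
  expect_equal(fitStatistics(m50)$f_df1, 24)
  expect_equal(fitStatistics(m50)$f_df2, 25)

  # perfect linear response: R^2 = 1, zero residual scale
  yp <- as.vector(scale(x[, 1]))
  mp <- suppressWarnings(olsFit(makeDesign(x, yp), "v1"))
  expect_equal(fitStatistics(mp)$r_squared, 1, tolerance = 1e-12)
  expect_lt(fitStatistics(mp)$sigma, 1e-10)
})

test_that("standardized coefficients are invariant to raw predictor scaling", {
  cfg <- generatorConfig(n_subjects = 25, n_nodes = 12, backbone_edges = 20,
                         n_noise_edges = 6, effect_nodes = 3L, seed = 73)
  gen <- generateCohort(cfg)
  nets <- lapply(connectomes(gen$cohort), binarizeTopK, k = 20L)
  met <- computeCohortMetrics(nets, subjectIds(gen$cohort),
                              regions(gen$cohort), n_random = 2, seed = 7)
  met_scaled <- met
  SummarizedExperiment::assay(met_scaled, "betweenness") <-
    SummarizedExperiment::assay(met, "betweenness") * 37.5
  d1 <- suppressWarnings(assembleDesign(met, gen$cohort))
  d2 <- suppressWarnings(assembleDesign(met_scaled, gen$cohort))
  preds <- colnames(d1$x)[1:6]
  m1 <- olsFit(d1, preds)
  m2 <- olsFit(d2, preds)
  expect_equal(coefficientTable(m1)$beta, coefficientTable(m2)$beta,
               tolerance = 1e-10)
})

test_that("Cook's distances match leave-one-out refits and catch a planted outlier", {
  set.seed(830)
  n <- 25; p <- 3
  x <- scale(matrix(rnorm(n * p), n, dimnames = list(NULL, c("a", "b", "c"))))
  y <- as.vector(scale(x %*% c(1, -1, 0.5) + rnorm(n, sd = 0.3)))
  model <- olsFit(makeDesign(x, y), c("a", "b", "c"))
  fit <- model@provenance$lm_fit
  d_pkg <- unname(cooks.distance(fit))
  pprime <- p + 1
  s2 <- summary(fit)$sigma^2
  d_loo <- vapply(seq_len(n), function(i) {
    fit_i <- lm(y[-i] ~ x[-i, , drop = FALSE])
    yhat_full <- fitted(fit)
    yhat_i <- cbind(1, x) %*% coef(fit_i)
    sum((yhat_full - yhat_i)^2) / (pprime * s2)
  }, numeric(1))
  expect_equal(d_pkg, d_loo, tolerance = 1e-8)

  # displace one response by 10 SD: exactly that subject is flagged
  y_out <- y
  y_out[13] <- y_out[13] + 10
  m_out <- olsFit(makeDesign(x, y_out), c("a", "b", "c"))
  flagged <- cooksFilter(m_out, multiplier = 3)
  expect_identical(flagged, "s013")
  refit <- olsFit(makeDesign(x, y_out),
                  c("a", "b", "c"),
                  subjects = setdiff(sprintf("s%03d", 1:n), flagged))
  clean <- olsFit(makeDesign(x, y), c("a", "b", "c"))
  expect_equal(coefficientTable(refit)$beta[2],
               coefficientTable(clean)$beta[2], tolerance = 0.05)
})

test_that("the full association stage is deterministic under a fixed seed", {
  cfg <- generatorConfig(n_subjects = 30, n_nodes = 12, backbone_edges = 20,
                         n_noise_edges = 6, effect_nodes = c(3L, 9L),
                         gamma = c(1, -1), seed = 74)
  gen <- generateCohort(cfg)
  nets <- lapply(connectomes(gen$cohort), binarizeTopK, k = 20L)
  met <- computeCohortMetrics(nets, subjectIds(gen$cohort),
                              regions(gen$cohort), n_random = 3, seed = 8)
  m1 <- suppressWarnings(runAssociation(met, gen$cohort, seed = 15))
  m2 <- suppressWarnings(runAssociation(met, gen$cohort, seed = 15))
  expect_equal(coefficientTable(m1), coefficientTable(m2))
  expect_identical(removedSubjects(m1), removedSubjects(m2))
  expect_identical(selectedPredictors(m1), selectedPredictors(m2))
  # age and sex always reach the final model even if unselected
  expect_true(all(c("age", "sex") %in% coefficientTable(m1)$term))
})
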