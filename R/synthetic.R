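#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the statistical structure the downstream analysis
#' assumes: a cohort of weighted connectomes sharing a sparse connected
#' backbone with subject-level multiplicative noise; a latent per-subject
#' factor z that scales every edge incident to designated effect nodes by
#' \code{exp(gamma * z)} (so those nodes' betweenness after top-K
#' binarization tracks z); covariates (age uniform on \code{age_range},
#' sex Bernoulli); and a multi-item trait questionnaire whose items are
#' discretized equicorrelated latent normals loading on z through
#' \code{beta_trait}, with the summed score rescaled at the cohort level to
#' target \code{trait_mean} and \code{trait_sd}.
#'
#' Defaults mirror a cohort of 51 subjects with 83-node connectomes, a
#' 343-edge backbone (mean binarized degree about 8.3), a 12-item trait
#' scale with latent inter-item correlation 0.262 (Spearman-Brown internal
#' consistency about 0.81 before discretization), trait mean 23.5 and SD
#' 7.5, ages 20-65 and a 33/51 male fraction.
#'
#' @param n_subjects cohort size.
#' @param n_nodes nodes per connectome.
#' @param backbone_edges shared strong edges (>= n_nodes - 1 so the backbone
#'   can be connected).
#' @param backbone_weight_mean,backbone_weight_sd mean and SD of the
#'   log-normal backbone weight distribution.
#' @param noise_weight_mean,noise_weight_sd mean and SD of the log-normal
#'   weights on spurious non-backbone edges.
#' @param n_noise_edges spurious subject-specific edges per subject.
#' @param edge_noise_sd SD of the mean-1 log-normal multiplicative noise
#'   applied independently to every backbone weight per subject.
#' @param effect_nodes integer vector of effect-node indices (1-based).
#' @param gamma signed edge-scaling effect size; scalar or one value per
#'   effect node (negative values plant negative trait associations).
#' @param beta_trait loading of the trait items' common factor on z.
#' @param trait_mean,trait_sd cohort-level targets for the rescaled score.
#' @param n_items number of questionnaire items (responses 0..4).
#' @param interitem_corr latent pairwise inter-item correlation in (0, 1).
#' @param age_range length-2 numeric, years.
#' @param sex_prob_male probability a subject is male.
#' @param seed integer master seed.
#' @return a validated list of class \code{"generatorConfig"}.
#' @export
generatorConfig <- function(n_subjects = 51L, n_nodes = 83L,
                            backbone_edges = 343L,
                            backbone_weight_mean = 10,
                            backbone_weight_sd = 5,
                            noise_weight_mean = 1, noise_weight_sd = 0.5,
                            n_noise_edges = 40L, edge_noise_sd = 0.3,
                            effect_nodes = c(17L, 64L),
                            gamma = c(0.8, -0.8),
                            beta_trait = 1.5,
                            trait_mean = 23.5, trait_sd = 7.5,
                            n_items = 12L, interitem_corr = 0.262,
                            age_range = c(20, 65),
                            sex_prob_male = 33 / 51,
                            seed = NULL) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_nodes = as.integer(n_nodes),
              backbone_edges = as.integer(backbone_edges),
              backbone_weight_mean = backbone_weight_mean,
              backbone_weight_sd = backbone_weight_sd,
              noise_weight_mean = noise_weight_mean,
              noise_weight_sd = noise_weight_sd,
              n_noise_edges = as.integer(n_noise_edges),
              edge_noise_sd = edge_noise_sd,
              effect_nodes = as.integer(effect_nodes),
              gamma = rep_len(gamma, length(effect_nodes)),
              beta_trait = beta_trait,
              trait_mean = trait_mean, trait_sd = trait_sd,
              n_items = as.integer(n_items),
              interitem_corr = interitem_corr,
              age_range = as.numeric(age_range),
              sex_prob_male = sex_prob_male,
              seed = seed)
  maxe <- cfg$n_nodes * (cfg$n_nodes - 1) / 2
  stopifnot(cfg$n_subjects >= 1L, cfg$n_nodes >= 2L,
            cfg$backbone_edges <= maxe,
            all(cfg$effect_nodes >= 1L & cfg$effect_nodes <= cfg$n_nodes),
            cfg$backbone_weight_sd > 0, cfg$noise_weight_sd > 0,
            cfg$edge_noise_sd > 0, cfg$trait_sd > 0,
            cfg$interitem_corr > 0, cfg$interitem_corr < 1,
            cfg$n_items >= 2L, diff(cfg$age_range) > 0,
            cfg$sex_prob_male >= 0, cfg$sex_prob_male <= 1)
  class(cfg) <- c("generatorConfig", "list")
  cfg
}

lnormParams <- function(m, s) {
  sdlog <- sqrt(log(1 + (s / m)^2))
  list(meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

syntheticRegions <- function(n_nodes) {
  if (n_nodes == 83L) defaultRegionTable()
  else regionTable(sprintf("node_%03d", seq_len(n_nodes)),
                   rep("none", n_nodes))
}

#' Generate the shared backbone connectome
#'
#' Chooses \code{backbone_edges} node pairs uniformly at random among all
#' pairs, constrained to form a connected graph (uniform resampling with a
#' bounded retry count; if no connected draw occurs — inevitable near the
#' spanning-tree limit — a uniform random spanning tree is drawn first and
#' the remaining edges are sampled uniformly). Backbone pairs carry
#' log-normal weights; all other pairs are 0.
#'
#' @param config a [generatorConfig()].
#' @param seed integer seed.
#' @param max_retry uniform resampling attempts before the spanning-tree
#'   construction.
#' @return a [WeightedConnectome-class] with subject id "backbone".
#' @export
generateBackbone <- function(config, seed = NULL, max_retry = 100L) {
  n <- config$n_nodes
  m <- config$backbone_edges
  if (m < n - 1L)
    stop("backbone_edges < n_nodes - 1: a connected backbone is unattainable")
  pr <- allPairs(n)
  withSeed(seed, {
    sel <- NULL
    for (try in seq_len(max_retry)) {
      cand <- sort(sample.int(nrow(pr), m))
      g <- igraph::graph_from_edgelist(pr[cand, , drop = FALSE],
                                       directed = FALSE)
      if (igraph::vcount(g) == n && igraph::is_connected(g)) {
        sel <- cand; break
      }
    }
    if (is.null(sel)) {
      tree <- igraph::as_edgelist(igraph::sample_tree(n, directed = FALSE),
                                  names = FALSE)
      tree_idx <- pairIndex(pmin(tree[, 1L], tree[, 2L]),
                            pmax(tree[, 1L], tree[, 2L]), n)
      rest <- setdiff(seq_len(nrow(pr)), tree_idx)
      extra <- if (m > n - 1L) sample(rest, m - (n - 1L)) else integer()
      sel <- sort(c(tree_idx, extra))
    }
    lp <- lnormParams(config$backbone_weight_mean, config$backbone_weight_sd)
    w <- matrix(0, n, n)
    e <- pr[sel, , drop = FALSE]
    wt <- rlnorm(m, lp$meanlog, lp$sdlog)
    w[e] <- wt
    w[e[, 2:1, drop = FALSE]] <- wt
    newConnectome("backbone", w, syntheticRegions(n), "synthetic")
  })
}

#' Generate one subject's connectome from the backbone
#'
#' Each backbone weight is multiplied by an independent mean-1 log-normal
#' noise factor; every edge incident to an effect node v is additionally
#' scaled by \code{exp(gamma_v * z_s)} (an edge between two effect nodes
#' receives both factors); and \code{n_noise_edges} random non-backbone
#' pairs receive spurious log-normal weights. Random draws do not depend on
#' gamma, so runs with different effect sizes under one seed are matched.
#'
#' @param backbone [WeightedConnectome-class] from [generateBackbone()].
#' @param z_s the subject's latent factor.
#' @param config a [generatorConfig()].
#' @param seed integer seed.
#' @param subject_id id for the returned connectome.
#' @return a [WeightedConnectome-class].
#' @export
generateSubject <- function(backbone, z_s, config, seed = NULL,
                            subject_id = "subject") {
  stopifnot(is.finite(z_s))
  n <- config$n_nodes
  wb <- backbone@weights
  withSeed(seed, {
    pr <- allPairs(n)
    on_bb <- wb[pr] > 0
    w <- matrix(0, n, n)
    # multiplicative subject noise on backbone edges
    lp <- lnormParams(1, config$edge_noise_sd)
    fac <- rlnorm(sum(on_bb), lp$meanlog, lp$sdlog)
    e <- pr[on_bb, , drop = FALSE]
    wt <- wb[e] * fac
    w[e] <- wt
    w[e[, 2:1, drop = FALSE]] <- wt
    # spurious subject-specific edges off the backbone
    off <- which(!on_bb)
    k <- min(config$n_noise_edges, length(off))
    if (k > 0L) {
      ln <- lnormParams(config$noise_weight_mean, config$noise_weight_sd)
      pick <- pr[sample(off, k), , drop = FALSE]
      nw <- rlnorm(k, ln$meanlog, ln$sdlog)
      w[pick] <- nw
      w[pick[, 2:1, drop = FALSE]] <- nw
    }
    # effect-node scaling, deterministic in z_s so draws are matched
    # across gamma settings; an edge between two effect nodes gets both
    # factors
    f <- rep(1, n)
    f[config$effect_nodes] <- exp(config$gamma * z_s)
    w <- w * outer(f, f)
    diag(w) <- 0
    newConnectome(subject_id, w, backbone@regions, "synthetic")
  })
}

ITEM_CATEGORY_PROBS <- c(0.1, 0.2, 0.4, 0.2, 0.1)

#' Generate item responses and a raw trait score for one subject
#'
#' Items discretize equicorrelated latent normals (pairwise correlation
#' \code{interitem_corr}) whose common factor is
#' \code{(beta_trait * z_s + u) / sqrt(beta_trait^2 + 1)} with u standard
#' normal, cut at fixed quantile thresholds giving marginal category
#' probabilities (0.1, 0.2, 0.4, 0.2, 0.1) over the ordered categories 0..4.
#' The returned \code{trait_score} is the raw item sum; [generateCohort()]
#' applies the cohort-level linear rescale to the configured mean and SD.
#' Age and sex are accepted for interface symmetry but carry no loading in
#' this trait model.
#'
#' @param z_s latent factor.
#' @param age,sex covariates (unused by the default trait model).
#' @param config a [generatorConfig()].
#' @param seed integer seed.
#' @return list with \code{item_responses} (integers 0..4) and
#'   \code{trait_score} (raw item sum).
#' @export
generateTrait <- function(z_s, age = NULL, sex = NULL, config, seed = NULL) {
  rho <- config$interitem_corr
  bt <- config$beta_trait
  cuts <- qnorm(cumsum(ITEM_CATEGORY_PROBS)[-5L])
  withSeed(seed, {
    u <- rnorm(1)
    common <- (bt * z_s + u) / sqrt(bt^2 + 1)
    latent <- sqrt(rho) * common + sqrt(1 - rho) * rnorm(config$n_items)
    items <- findInterval(latent, cuts)
    list(item_responses = as.integer(items),
         trait_score = sum(items))
  })
}

#' Generate a full synthetic cohort with ground truth
#'
#' Draws a per-subject latent factor z ~ N(0,1), ages uniform on
#' \code{age_range}, sex Bernoulli(\code{sex_prob_male}); builds the shared
#' backbone and per-subject connectomes; generates item responses and
#' rescales the summed scores linearly so the cohort matches
#' \code{trait_mean} / \code{trait_sd} exactly. Per-stage sub-seeds are
#' derived from \code{config$seed}, so the run is deterministic.
#'
#' @param config a [generatorConfig()].
#' @return list with \code{cohort} (a [ConnectomeCohort-class]) and
#'   \code{ground_truth} (z, effect nodes, gamma, beta_trait, backbone edge
#'   list, seed).
#' @export
generateCohort <- function(config = generatorConfig()) {
  ns <- config$n_subjects
  seeds <- if (is.null(config$seed)) rep(list(NULL), 3L + 2L * ns)
           else as.list(deriveSeeds(config$seed, 3L + 2L * ns))
  backbone <- generateBackbone(config, seed = seeds[[1L]])
  z <- withSeed(seeds[[2L]], rnorm(ns))
  covd <- withSeed(seeds[[3L]], {
    data.frame(
      subject_id = sprintf("sub-%03d", seq_len(ns)),
      age = runif(ns, config$age_range[1L], config$age_range[2L]),
      sex = ifelse(rbinom(ns, 1L, config$sex_prob_male) == 1L,
                   "male", "female"),
      stringsAsFactors = FALSE)
  })
  cons <- vector("list", ns)
  items <- matrix(0L, ns, config$n_items,
                  dimnames = list(NULL, paste0("item_", seq_len(config$n_items))))
  raw <- numeric(ns)
  for (s in seq_len(ns)) {
    cons[[s]] <- generateSubject(backbone, z[s], config,
                                 seed = seeds[[3L + s]],
                                 subject_id = covd$subject_id[s])
    tr <- generateTrait(z[s], covd$age[s], covd$sex[s], config,
                        seed = seeds[[3L + ns + s]])
    items[s, ] <- tr$item_responses
    raw[s] <- tr$trait_score
  }
  names(cons) <- covd$subject_id
  score <- if (ns > 1L && sd(raw) > 0)
    (raw - mean(raw)) / sd(raw) * config$trait_sd + config$trait_mean
  else rep(config$trait_mean, ns)
  covd$trait_score <- score
  cohort <- new("ConnectomeCohort", connectomes = cons,
                covariates = covd, items = items)
  gt <- list(z = z,
             effect_nodes = config$effect_nodes,
             gamma = config$gamma,
             beta_trait = config$beta_trait,
             backbone_edges = {
               wb <- backbone@weights
               pr <- allPairs(config$n_nodes)
               pr[wb[pr] > 0, , drop = FALSE]
             },
             seed = config$seed)
  list(cohort = cohort, ground_truth = gt)
}
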