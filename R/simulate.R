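# Synthetic trait-evolution generator: pure-birth trees, Brownian and
# Markov trait simulation with phylogenetically structured residuals, and
# planted-error injection for QC recovery experiments.

#' Simulation configuration
#'
#' Bundles the true parameter set for synthetic data generation and
#' recovery experiments. Defaults mirror the conditions of the headline
#' among-vertebrate analysis: regression truths beta = (0.648 body,
#' 0.286 newborn, 0.187 body temperature, 0.109 interaction) on the
#' scaled scale, phylogenetic signal lambda_true = 0.97 with
#' sigma2_phylo = 0.97 and sigma2_res = 0.03, an ordered egg-care factor
#' whose effects increase monotonically from abandoning to provisioning,
#' and Brownian body mass on a 100-Myr pure-birth tree.
#'
#' @param n_species Number of tips (>= 2).
#' @param tree_model `"pure_birth"` (a fixed tree can be passed directly
#'   to [simulate_traits()]).
#' @param birth_rate Speciation rate of the pure-birth process.
#' @param root_age Tree depth in Myr after rescaling.
#' @param lambda_true Pagel's lambda of the residual structure, in \[0,1\].
#' @param beta Named numeric: `body`, `newborn`, `temp`, `interaction`.
#' @param care_effect Named per-level shift (log10 units) on relative
#'   newborn mass, `abandon`, `guard`, `bear`, `provision`.
#' @param sigma2_phylo,sigma2_res Phylogenetic and residual variance of
#'   the brain response.
#' @param sigma2_body Brownian rate of log10 body mass per Myr.
#' @param newborn_slope Allometric slope of log10 newborn on log10 body.
#' @param sigma_newborn Residual SD of log10 newborn mass.
#' @param class_temps Named list `class -> c(mean, sd)` of body
#'   temperature distributions (degrees C).
#' @param temp_heritability Fraction of temperature variance with
#'   phylogenetic structure.
#' @param care_transition Markov rate (per Myr) between adjacent care
#'   levels.
#' @param seed Integer seed; fixes the full output.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_species = 300,
                              tree_model = "pure_birth",
                              birth_rate = 1,
                              root_age = 100,
                              lambda_true = 0.97,
                              beta = c(body = 0.648, newborn = 0.286,
                                       temp = 0.187, interaction = 0.109),
                              care_effect = c(abandon = 0, guard = 0.25,
                                              bear = 0.5, provision = 0.8),
                              sigma2_phylo = 0.97,
                              sigma2_res = 0.03,
                              sigma2_body = 0.01,
                              newborn_slope = 0.75,
                              sigma_newborn = 0.3,
                              class_temps = list(
                                Vertebrata = c(mean = 25, sd = 6)),
                              temp_heritability = 0.5,
                              care_transition = 0.02,
                              seed = 1L) {
  stopifnot(n_species >= 2, sigma2_phylo >= 0, sigma2_res > 0,
            sigma2_body > 0, sigma_newborn > 0, birth_rate > 0,
            root_age > 0, temp_heritability >= 0, temp_heritability <= 1,
            care_transition >= 0)
  if (lambda_true < 0 || lambda_true > 1) stop("lambda_true must be in [0,1]")
  need <- c("body", "newborn", "temp", "interaction")
  if (!all(need %in% names(beta))) {
    stop("beta must name: ", paste(need, collapse = ", "))
  }
  lv <- c("abandon", "guard", "bear", "provision")
  if (!all(lv %in% names(care_effect))) {
    stop("care_effect must name: ", paste(lv, collapse = ", "))
  }
  structure(list(n_species = as.integer(n_species),
                 tree_model = tree_model, birth_rate = birth_rate,
                 root_age = root_age, lambda_true = lambda_true,
                 beta = beta[need], care_effect = care_effect[lv],
                 sigma2_phylo = sigma2_phylo, sigma2_res = sigma2_res,
                 sigma2_body = sigma2_body, newborn_slope = newborn_slope,
                 sigma_newborn = sigma_newborn, class_temps = class_temps,
                 temp_heritability = temp_heritability,
                 care_transition = care_transition,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate an ultrametric pure-birth tree
#'
#' Pure-birth (Yule) tree with `n_species` tips, rescaled so the root age
#' equals `config$root_age` Myr. Deterministic under the config seed.
#'
#' @param config A [simulation_config()].
#' @return An ultrametric `phylo`.
#' @export
simulate_tree <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$n_species < 2) stop("need at least 2 species")
  set.seed(config$seed)
  tr <- ape::rphylo(config$n_species, birth = config$birth_rate, death = 0)
  tr$edge.length <- tr$edge.length * (config$root_age / tree_height(tr))
  tr
}

#' Simulate a species trait table on a tree
#'
#' Generates, in order: log10 body mass by Brownian motion; an ordered
#' 4-level egg-care state by a stepwise Markov jump process; log10
#' newborn mass as an allometric function of body mass shifted upward by
#' care level, with phylogenetically structured noise; body temperature
#' per class (clade membership from a grafted supertree's `clade`
#' attribute, otherwise a single class) with a heritable component; and
#' the brain response as
#' `beta_body*z(body) + beta_NM*z(newborn) + beta_Tb*z(temp) +
#' beta_int*z(newborn)*z(temp) + u + e` with
#' `u ~ N(0, sigma2_phylo * A(lambda_true))` and
#' `e ~ N(0, sigma2_res * I)`. Predictors are standardized inside the
#' generator, so the configured betas are the exact truths recovered by
#' modeling the log10 masses with z-scored predictors.
#'
#' @param tree An ultrametric `phylo` (e.g. from [simulate_tree()] or
#'   [graft_supertree()]).
#' @param config A [simulation_config()].
#' @return Data frame (`species`, `class_name`, `body_mass_g`,
#'   `newborn_mass_g`, `brain_mass_g`, `care_level`, `body_temp_C`) with
#'   attribute `truth` logging every generating value.
#' @export
simulate_traits <- function(tree, config) {
  stopifnot(inherits(config, "simulation_config"), inherits(tree, "phylo"))
  validate_ultrametric(tree)
  set.seed(config$seed + 1L)
  n <- ape::Ntip(tree)
  taxa <- tree$tip.label
  h <- tree_height(tree)
  V <- ape::vcv(tree)[taxa, taxa]
  Ccor <- V / h                       # unit-diagonal correlation form
  Lc <- chol_psd(Ccor)

  cls <- attr(tree, "clade")
  if (is.null(cls)) cls <- setNames(rep(names(config$class_temps)[1], n),
                                    taxa)
  cls <- cls[taxa]
  if (!all(cls %in% names(config$class_temps))) {
    stop("class labels without a class_temps entry: ",
         paste(setdiff(unique(cls), names(config$class_temps)),
               collapse = ", "))
  }

  # body mass: BM with rate sigma2_body per Myr around a 1 kg ancestor
  body_log10 <- 3 + drop(crossprod(Lc, rnorm(n))) *
    sqrt(config$sigma2_body * h)

  # egg care: stepwise Markov process on the ordered levels
  lv <- c("abandon", "guard", "bear", "provision")
  care <- simulate_care(tree, rate = config$care_transition, levels = lv)

  # newborn mass: allometry + care shift + structured noise
  nb_noise <- mix_noise(Lc, n, sd = config$sigma_newborn, phylo_frac = 0.5)
  newborn_log10 <- -0.5 + config$newborn_slope * (body_log10 - 3) +
    config$care_effect[care] + nb_noise

  # body temperature per class, partially heritable
  tmp <- config$class_temps
  t_mean <- vapply(cls, function(k) tmp[[k]]["mean"], numeric(1))
  t_sd <- vapply(cls, function(k) tmp[[k]]["sd"], numeric(1))
  hb <- drop(crossprod(Lc, rnorm(n)))
  temp_C <- t_mean + t_sd * (sqrt(config$temp_heritability) * hb +
    sqrt(1 - config$temp_heritability) * rnorm(n))

  # population-SD z-scores, matching prepare_model_frame()
  zscore_pop <- function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  zb <- zscore_pop(body_log10)
  zn <- zscore_pop(newborn_log10)
  zt <- zscore_pop(temp_C)
  Llam <- chol_psd(lambda_transform(Ccor, config$lambda_true))
  u <- drop(crossprod(Llam, rnorm(n))) * sqrt(config$sigma2_phylo)
  e <- rnorm(n, sd = sqrt(config$sigma2_res))
  b <- config$beta
  brain <- b["body"] * zb + b["newborn"] * zn + b["temp"] * zt +
    b["interaction"] * zn * zt + u + e

  out <- data.frame(species = taxa, class_name = unname(cls),
                    body_mass_g = 10^body_log10,
                    newborn_mass_g = 10^newborn_log10,
                    brain_mass_g = 10^unname(brain),
                    care_level = unname(care),
                    body_temp_C = unname(temp_C),
                    stringsAsFactors = FALSE)
  rownames(out) <- taxa
  attr(out, "truth") <- list(beta = b, lambda = config$lambda_true,
                             sigma2_phylo = config$sigma2_phylo,
                             sigma2_res = config$sigma2_res,
                             care_effect = config$care_effect,
                             seed = config$seed)
  out
}

# upper Cholesky factor tolerant of the near-PSD matrices a lambda
# transform can produce
chol_psd <- function(M) {
  ok <- tryCatch(chol(M), error = function(e) NULL)
  if (!is.null(ok)) return(ok)
  eg <- eigen(M, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  t(eg$vectors %*% (t(eg$vectors) * sqrt(vals)))
}

# half-phylogenetic, half-independent Gaussian noise
mix_noise <- function(Lc, n, sd, phylo_frac) {
  sd * (sqrt(phylo_frac) * drop(crossprod(Lc, rnorm(n))) +
          sqrt(1 - phylo_frac) * rnorm(n))
}

# stepwise (adjacent-state) Markov evolution of the care factor
simulate_care <- function(tree, rate, levels) {
  k <- length(levels)
  if (rate <= 0) {
    return(setNames(rep(levels[1], ape::Ntip(tree)), tree$tip.label))
  }
  Q <- matrix(0, k, k)
  for (i in seq_len(k - 1)) {
    Q[i, i + 1] <- rate
    Q[i + 1, i] <- rate
  }
  diag(Q) <- -rowSums(Q)
  st <- ape::rTraitDisc(tree, model = Q, states = levels,
                        root.value = 1, ancestor = FALSE)
  setNames(as.character(st), tree$tip.label)
}

#' Plant multiplicative brain-mass errors
#'
#' Multiplies the brain mass of a random species subset by `factor` and
#' records the ground truth, to measure QC-filter recall.
#'
#' @param table A trait table (needs `species` and `brain_mass_g`).
#' @param frac Fraction of species altered, in \[0, 0.2\] (larger
#'   contamination would distort the very regressions the filter uses).
#' @param factor Multiplicative error.
#' @param seed Integer seed.
#' @return The altered table with attribute `outlier_species` (character
#'   vector of altered species).
#' @export
inject_outliers <- function(table, frac, factor, seed = 1L) {
  stopifnot(is.data.frame(table), "brain_mass_g" %in% names(table))
  if (frac < 0 || frac > 0.2) {
    stop("frac must lie in [0, 0.2]")
  }
  set.seed(seed)
  n_out <- round(frac * nrow(table))
  idx <- if (n_out > 0) sample(nrow(table), n_out) else integer(0)
  table$brain_mass_g[idx] <- table$brain_mass_g[idx] * factor
  attr(table, "outlier_species") <- table$species[sort(idx)]
  table
}

#' Simulate specimen-level brain data for QC experiments
#'
#' Emulates a small-bodied ray-finned-fish assemblage, the data the
#' allometric QC filters were designed for: genera share a tight
#' log-brain on log-body allometry (slope 0.5, residual SD
#' `sigma_resid` log10 units), species body masses are ~100-2000 g and
#' brain masses ~0.1-0.6 g. On this scale a 3x brain-mass error reliably
#' leaves the genus-rule ratio band while clean species stay inside it.
#'
#' @param n_genera,species_per_genus,specimens_per_species Design sizes.
#' @param sigma_resid Within-genus allometric residual SD (log10 units).
#' @param seed Integer seed.
#' @return Data frame with `species`, `genus`, `body_mass_g`,
#'   `brain_mass_g`.
#' @export
simulate_specimens <- function(n_genera = 30, species_per_genus = 8,
                               specimens_per_species = 1,
                               sigma_resid = 0.05, seed = 1L) {
  set.seed(seed)
  rows <- list()
  for (g in seq_len(n_genera)) {
    a_g <- rnorm(1, -0.675, 0.05)
    for (s in seq_len(species_per_genus)) {
      lb_sp <- rnorm(1, 2.5, 0.2)
      for (r in seq_len(specimens_per_species)) {
        lb <- lb_sp + rnorm(1, 0, 0.02)
        lbr <- a_g + 0.5 * (lb - 2.5) + rnorm(1, 0, sigma_resid)
        rows[[length(rows) + 1L]] <- data.frame(
          species = sprintf("g%02d_sp%02d", g, s),
          genus = sprintf("g%02d", g),
          body_mass_g = 10^lb, brain_mass_g = 10^lbr,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Simulate data from a causal DAG with phylogenetic noise
#'
#' Generates each node in topological order as the coefficient-weighted
#' sum of its parents plus Gaussian noise with Pagel's-lambda
#' phylogenetic structure, for path-analysis recovery experiments.
#'
#' @param dag A `causal_dag`.
#' @param coefs Named numeric vector of edge coefficients, names
#'   `"from->to"`; missing edges get `default_coef`.
#' @param cov A phylogenetic covariance ([shared_path_covariance()]).
#' @param lambda Pagel's lambda of every node's noise.
#' @param sigma Noise SD per node.
#' @param default_coef Coefficient for edges not named in `coefs`.
#' @param seed Integer seed.
#' @return Data frame with one column per node, rows in `cov` taxa order.
#' @export
simulate_path_data <- function(dag, coefs = numeric(0), cov, lambda = 0.9,
                               sigma = 1, default_coef = 0.5, seed = 1L) {
  stopifnot(inherits(dag, "causal_dag"))
  M <- cov_matrix(cov)
  d0 <- diag(M)
  Ccor <- M / sqrt(d0 %o% d0)
  n <- nrow(Ccor)
  set.seed(seed)
  L <- chol_psd(lambda_transform(Ccor, lambda))
  out <- as.data.frame(matrix(NA_real_, n, length(dag$nodes),
                              dimnames = list(rownames(M), dag$nodes)))
  for (v in dag$order) {
    val <- drop(crossprod(L, rnorm(n))) * sigma
    for (p_ in dag$parents[[v]]) {
      key <- paste0(p_, "->", v)
      cf <- if (key %in% names(coefs)) coefs[[key]] else default_coef
      val <- val + cf * out[[p_]]
    }
    out[[v]] <- val
  }
  out
}
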