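test_that("chain bookkeeping follows the stated settings", {
  ch <- chain_spec()
  expect_equal(ch$iterations, 500000L)
  expect_equal(ch$burn_in, 100000L)
  expect_equal(ch$thin, 40L)
  expect_equal(ch$stored, 10000L)
  expect_error(chain_spec(1000, 2000, 10), "smaller")
  expect_error(chain_spec(1000, 100, 7), "divisible")
  ch2 <- chain_spec(5000, 1000, 4)
  expect_equal(ch2$stored, 1000L)
})

test_that("p_mcmc is the floored two-sided sign fraction", {
  expect_equal(p_mcmc(rep(1, 10000)), 1e-4)
  expect_equal(p_mcmc(c(rep(1, 500), rep(-1, 500))), 1)
  expect_equal(p_mcmc(c(rep(1, 9900), rep(-1, 100))), 0.02)
  expect_error(p_mcmc(1), "at least 2")
})

test_that("effective_sample_size matches iid and AR(1) expectations", {
  set.seed(101)
  x <- rnorm(10000)
  ess <- effective_sample_size(x)
  expect_gte(ess, 9000); expect_lte(ess, 10000)
  # AR(1) with rho = 0.9: ESS ~= n (1 - rho) / (1 + rho)
  rho <- 0.9; n <- 20000
  ar <- as.numeric(arima.sim(list(ar = rho), n))
  expect_equal(effective_sample_size(ar), n * (1 - rho) / (1 + rho),
               tolerance = 0.2)
  expect_warning(ess0 <- effective_sample_size(rep(2, 10)), "constant")
  expect_equal(ess0, 0)
  expect_error(effective_sample_size(rnorm(5)), "at least 10")
})

test_that("phylo_signal is the per-draw variance ratio", {
  expect_equal(phylo_signal(c(1, 2, 3), c(1, 2, 3))$mean, 0.5)
  expect_equal(phylo_signal(rep(0, 5), rep(1, 5))$mean, 0)
  expect_error(phylo_signal(c(0, 1), c(0, 1)), "both variances zero")
  # gamma-draw mean against a large independent Monte-Carlo oracle
  set.seed(33)
  a <- rgamma(5000, 2, 1); b <- rgamma(5000, 3, 1)
  big_a <- rgamma(4e5, 2, 1); big_b <- rgamma(4e5, 3, 1)
  expect_equal(phylo_signal(a, b)$mean, mean(big_a / (big_a + big_b)),
               tolerance = 0.01)
  # scale invariance: the ratio cancels any rescaling of y
  expect_equal(phylo_signal(7 * a, 7 * b)$draws,
               phylo_signal(a, b)$draws)
})

test_that("without a phylogenetic effect the posterior matches the conjugate closed form", {
  set.seed(55)
  n <- 80
  star <- ape::stree(n, "star"); star$edge.length <- rep(1, n)
  star$tip.label <- paste0("t", seq_len(n))
  cv <- shared_path_covariance(star)
  x <- rnorm(n); y <- 1 + 0.6 * x + rnorm(n, 0, 0.5)
  fr <- data.frame(y = y, x = x, row.names = star$tip.label)
  pr <- prior_spec(residual_V = 1, residual_nu = 0.002, beta_prec = 0)
  fit <- fit_pglmm(y ~ x, fr, cv, priors = pr,
                   chain = chain_spec(22000, 2000, 2, seed = 1),
                   include_phylo = FALSE)
  X <- cbind(1, x)
  bhat <- solve(crossprod(X), crossprod(X, y))
  # flat-prior conjugate posterior: E[beta] = OLS, and
  # Var(beta) = E[sigma2] (X'X)^-1 with sigma2 ~ IG(a + (n-p)/2, b + RSS/2)
  a0 <- 0.002 / 2; b0 <- 0.002 / 2
  rss <- sum((y - X %*% bhat)^2)
  es2 <- (b0 + rss / 2) / (a0 + (n - 2) / 2 - 1)
  vb <- es2 * solve(crossprod(X))
  draws <- fit$samples[, 1:2]
  mcse <- apply(draws, 2, sd) / sqrt(effective_sample_size(draws[, 2]))
  expect_lt(abs(mean(draws[, 1]) - bhat[1]), 3 * mcse[1] + 1e-3)
  expect_lt(abs(mean(draws[, 2]) - bhat[2]), 3 * mcse[2] + 1e-3)
  expect_equal(var(draws[, 2]), vb[2, 2], tolerance = 0.15)
  expect_equal(mean(fit$samples[, "sigma2_res"]), es2, tolerance = 0.1)
  expect_equal(fit$lambda_signal$mean, 0)
})

test_that("simulation-based calibration ranks are uniform", {
  # datasets drawn from the sampler's own proper prior; if the Gibbs
  # transitions are correct, the rank of each true beta among posterior
  # draws is uniform
  set.seed(202)
  tr <- rand_tree(50, height = 100)
  cv <- precompute_eigen(shared_path_covariance(tr))
  A <- cv$matrix / 100
  LA <- chol_psd_test(A)
  n <- 50
  xfix <- rnorm(n)
  X <- cbind(1, xfix)
  pr <- prior_spec(residual_V = 0.5, residual_nu = 4,
                   phylo_V = 0.5, phylo_nu = 4,
                   alpha_mu = 0, alpha_V = 1, beta_prec = 1)
  nset <- 120
  ranks <- matrix(NA_real_, nset, 2)
  fr <- data.frame(y = rnorm(n), x = xfix, row.names = tr$tip.label)
  for (s in seq_len(nset)) {
    beta_true <- rnorm(2, 0, 1)
    s2eta <- 1 / rgamma(1, 2, 1)  # IG(nu/2=2, nu*V/2=1)
    alpha <- rnorm(1, 0, 1)
    s2r <- 1 / rgamma(1, 2, 1)
    u <- alpha * drop(crossprod(LA, rnorm(n))) * sqrt(s2eta)
    fr$y <- drop(X %*% beta_true) + u + rnorm(n, 0, sqrt(s2r))
    fit <- fit_pglmm(y ~ x, fr, cv, priors = pr,
                     chain = chain_spec(4200, 200, 4, seed = s))
    ranks[s, 1] <- mean(fit$samples[, 1] < beta_true[1])
    ranks[s, 2] <- mean(fit$samples[, 2] < beta_true[2])
  }
  for (j in 1:2) {
    counts <- table(cut(ranks[, j], breaks = seq(0, 1, by = 0.1)))
    p <- chisq.test(as.numeric(counts))$p.value
    expect_gt(p, 0.01)
  }
})

test_that("posterior means are stable to doubled thinning at fixed draws", {
  set.seed(66)
  cfg <- simulation_config(n_species = 100, seed = 3)
  tr <- simulate_tree(cfg); tab <- simulate_traits(tr, cfg)
  cv <- precompute_eigen(shared_path_covariance(tr, tab$species))
  fr <- prepare_model_frame(tab, c("brain_mass_g", "body_mass_g"),
                            log10_vars = c("brain_mass_g", "body_mass_g"),
                            zscore = "body_mass_g", taxa_order = cv$taxa)
  f1 <- fit_pglmm(brain_mass_g ~ body_mass_g, fr, cv,
                  chain = chain_spec(22000, 2000, 10, seed = 5))
  f2 <- fit_pglmm(brain_mass_g ~ body_mass_g, fr, cv,
                  chain = chain_spec(42000, 2000, 20, seed = 5))
  expect_equal(f1$summary["body_mass_g", "posterior_mean"],
               f2$summary["body_mass_g", "posterior_mean"],
               tolerance = 0.05)
  expect_equal(nrow(f1$samples), 2000)
  expect_equal(nrow(f2$samples), 2000)
})

test_that("a short-chain fit recovers simulated truths within its interval", {
  cfg <- simulation_config(n_species = 150, seed = 7)
  tr <- simulate_tree(cfg); tab <- simulate_traits(tr, cfg)
  cv <- shared_path_covariance(tr, tab$species)
  fr <- prepare_model_frame(
    tab, c("brain_mass_g", "body_mass_g", "newborn_mass_g", "body_temp_C"),
    log10_vars = c("brain_mass_g", "body_mass_g", "newborn_mass_g"),
    zscore = c("body_mass_g", "newborn_mass_g", "body_temp_C"),
    interactions = "newborn_mass_g:body_temp_C", taxa_order = cv$taxa)
  names(fr)[names(fr) == "newborn_mass_g:body_temp_C"] <- "nm_tb"
  fit <- fit_pglmm(brain_mass_g ~ body_mass_g + newborn_mass_g +
                     body_temp_C + nm_tb, fr, cv,
                   chain = chain_spec(30000, 5000, 25, seed = 42))
  truth <- attr(tab, "truth")$beta
  s <- fit$summary
  for (pair in list(c("body_mass_g", "body"),
                    c("newborn_mass_g", "newborn"),
                    c("body_temp_C", "temp"),
                    c("nm_tb", "interaction"))) {
    expect_gt(truth[pair[2]], s[pair[1], "ci_lower"])
    expect_lt(truth[pair[2]], s[pair[1], "ci_upper"])
  }
  expect_gt(fit$lambda_signal$mean, 0.8)
  expect_equal(nrow(fit$samples), 1000)
})
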