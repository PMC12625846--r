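test_that("length_to_mass applies the allometric length-weight relation", {
  lw <- conversion_spec("length_weight", a = 0.01, b = 3)
  expect_equal(length_to_mass(10, lw), 10)
  expect_equal(length_to_mass(1, lw), 0.01)
  lw2 <- conversion_spec("length_weight", a = 0.0089, b = 3.1)
  expect_equal(length_to_mass(25, lw2), 0.0089 * exp(3.1 * log(25)))
  expect_error(length_to_mass(-1, lw), "positive")
  expect_error(conversion_spec("length_weight", a = -2, b = 3), "a > 0")
})

test_that("egg_diameter_to_mass is the density-1 sphere volume", {
  expect_equal(egg_diameter_to_mass(1), pi / 6)
  expect_equal(egg_diameter_to_mass(2), 8 * pi / 6)
  expect_equal(egg_diameter_to_mass(0.2), 1 * (pi / 6) * 0.2^3)
  expect_error(egg_diameter_to_mass(0), "positive")
  # strictly increasing, scaling as d^3 over a grid
  d <- seq(0.1, 5, length.out = 40)
  m <- egg_diameter_to_mass(d)
  expect_true(all(diff(m) > 0))
  expect_equal(m / m[1], (d / d[1])^3, tolerance = 1e-12)
})

test_that("egg_to_hatchling_mass applies the log10-linear regression", {
  sp <- conversion_spec("egg_to_hatchling", a = 0.936, b = -0.158)
  expect_equal(log10(egg_to_hatchling_mass(1, sp)), -0.158)
  expect_equal(egg_to_hatchling_mass(10, sp), 10^(0.936 - 0.158))
  ident <- conversion_spec("egg_to_hatchling", a = 1, b = 0)
  expect_equal(egg_to_hatchling_mass(c(0.5, 3, 42), ident), c(0.5, 3, 42))
  expect_equal(egg_to_hatchling_mass(7, conversion_spec("identity")), 7)
  expect_error(egg_to_hatchling_mass(0, sp), "positive")
})

test_that("fit_conversion_regression recovers log-linear relations", {
  egg <- c(1, 2, 5, 10, 50)
  hatch <- 10^(0.9 * log10(egg) - 0.1)
  fit <- fit_conversion_regression(egg, hatch)
  expect_equal(fit$a, 0.9, tolerance = 1e-10)
  expect_equal(fit$b, -0.1, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$n, 5L)
  expect_error(fit_conversion_regression(c(1, 1, 1), c(2, 2, 2)),
               "zero variance")
  expect_error(fit_conversion_regression(c(1, 2), c(1, 2)), "3 pairs")
})

test_that("noisy conversion regression matches the published-scale fit", {
  # sigma chosen so R^2 is near 0.97 with slope 0.936 over this x spread
  set.seed(11)
  n <- 453
  lx <- rnorm(n, 1, 0.5)
  sigma <- sqrt(0.936^2 * 0.25 * 0.03 / 0.97)
  ly <- 0.936 * lx - 0.158 + rnorm(n, 0, sigma)
  fit <- fit_conversion_regression(10^lx, 10^ly)
  expect_lt(abs(fit$a - 0.936), 0.02)
  expect_gt(fit$r_squared, 0.95)
})

test_that("qc_filter_brain species rule flags out-of-band specimens", {
  # five clean specimens on an exact allometry plus one depressed brain
  body <- 10^c(2, 2.5, 3, 3.5, 4, 3)
  brain <- 10^c(1, 1.25, 1.5, 1.75, 2, 0.9)
  spec <- data.frame(species = "sp1", genus = "g1",
                     body_mass_g = body, brain_mass_g = brain)
  res <- qc_filter_brain(spec)
  expect_equal(res$report$rule, "species")
  expect_equal(res$report$decision, "removed")
  expect_equal(nrow(res$kept), 0)

  # the same species without the aberrant specimen is kept
  res2 <- qc_filter_brain(spec[1:5, ])
  expect_equal(res2$report$decision, "kept")
  expect_equal(nrow(res2$removed), 0)
})

test_that("qc_filter_brain genus rule judges small species against the genus", {
  set.seed(3)
  base <- simulate_specimens(n_genera = 4, species_per_genus = 6, seed = 5)
  res <- qc_filter_brain(base)
  expect_true(all(res$report$rule == "genus"))
  expect_true(all(res$report$decision == "kept"))
  expect_true(all(res$report$ratio > 0.6 & res$report$ratio < 1.7))

  # genus too small for a regression: passed through flagged, never dropped
  tiny <- base[base$species %in% unique(base$species)[1:2] &
                 base$genus == base$genus[1], ]
  res3 <- qc_filter_brain(tiny)
  expect_true(all(res3$report$rule == "unfilterable"))
  expect_equal(nrow(res3$kept), nrow(tiny))
})

test_that("a planted 10x brain error is removed, and only it", {
  # noiseless genus on an exact allometry; the error is implanted at the
  # genus mean body mass (zero leverage) so the experiment isolates the
  # filter's decision rule from reference-fit contamination
  lb <- seq(2.2, 2.8, by = 0.05)
  spc <- data.frame(species = sprintf("gA_sp%d", seq_along(lb)),
                    genus = "gA",
                    body_mass_g = 10^lb,
                    brain_mass_g = 10^(-0.675 + 0.5 * (lb - 2.5)))
  victim <- "gA_sp7"  # the genus-mean body mass
  spc$brain_mass_g[spc$species == victim] <-
    spc$brain_mass_g[spc$species == victim] * 10
  res <- qc_filter_brain(spc)
  expect_equal(res$report$species[res$report$decision == "removed"],
               victim)
  expect_equal(nrow(res$kept), length(lb) - 1)
})

test_that("average_bmr keeps records within the mass window", {
  out <- average_bmr(c(85, 115, 130), c(10, 20, 100), 100)
  expect_equal(out$bmr_mean, 15)
  expect_equal(out$n_used, 2L)
  expect_equal(average_bmr(100, 7, 100)$bmr_mean, 7)
  expect_error(average_bmr(c(300, 400), c(1, 2), 100), "no BMR record within")
  expect_error(average_bmr(numeric(0), numeric(0), 100), "no BMR records")
  # brute-force oracle on simulated records
  set.seed(21)
  m <- runif(50, 50, 200); b <- rnorm(50, 10)
  keep <- m >= 80 & m <= 120
  expect_equal(average_bmr(m, b, 100)$bmr_mean, mean(b[keep]))
})

test_that("residualize returns OLS residuals orthogonal to x", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(residualize(2 * x + 1, x), rep(0, 5))
  # centered y orthogonal to x passes through unchanged
  y0 <- c(1, -1, 0, 0, 0); y0 <- y0 - mean(y0)
  y0 <- y0 - x * sum(y0 * (x - mean(x))) / sum((x - mean(x))^2)
  y0 <- y0 - mean(y0)
  expect_equal(residualize(y0, x), y0, tolerance = 1e-12)
  set.seed(5)
  y <- rnorm(20); x2 <- rnorm(20)
  r <- residualize(y, x2)
  X <- cbind(1, x2)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(r, y - drop(X %*% beta), tolerance = 1e-10)
  expect_lt(abs(sum(r)), 1e-8)
  expect_lt(abs(cor(r, x2)), 1e-10)
  expect_error(residualize(y, rep(1, 20)), "zero variance")
  expect_error(residualize(1:2, 1:2), "at least 3")
})

test_that("prepare_model_frame transforms in log10-then-zscore order", {
  tab <- data.frame(species = c("a", "b", "c"),
                    body_mass_g = c(10, 100, 1000),
                    body_temp_C = c(10, 20, 30))
  fr <- prepare_model_frame(tab, c("body_mass_g", "body_temp_C"),
                            log10_vars = "body_mass_g")
  expect_equal(fr$body_mass_g, c(-1.2247449, 0, 1.2247449),
               tolerance = 1e-6)
  # zscore off: log10 passes through
  fr2 <- prepare_model_frame(tab, "body_mass_g", log10_vars = "body_mass_g",
                             zscore = FALSE)
  expect_equal(fr2$body_mass_g, c(1, 2, 3))
})

test_that("model frame interactions, ordering and missing-data policy", {
  set.seed(2)
  tab <- data.frame(species = paste0("s", 1:20),
                    newborn_mass_g = 10^rnorm(20),
                    body_temp_C = rnorm(20, 25, 5))
  tab$body_temp_C[3] <- NA
  fr <- prepare_model_frame(tab, c("newborn_mass_g", "body_temp_C"),
                            log10_vars = "newborn_mass_g",
                            interactions = "newborn_mass_g:body_temp_C")
  expect_equal(attr(fr, "n_dropped"), 1L)
  expect_equal(fr[["newborn_mass_g:body_temp_C"]],
               fr$newborn_mass_g * fr$body_temp_C)
  for (v in c("newborn_mass_g", "body_temp_C")) {
    expect_lt(abs(mean(fr[[v]])), 1e-10)
    expect_equal(sqrt(mean(fr[[v]]^2)), 1, tolerance = 1e-10)
  }
  ord <- rev(fr$species)
  fr3 <- prepare_model_frame(tab, c("newborn_mass_g", "body_temp_C"),
                             taxa_order = ord)
  expect_identical(rownames(fr3), ord)
  expect_error(prepare_model_frame(tab, "nope"), "absent")
  tab$flat <- 1
  expect_error(prepare_model_frame(tab, "flat"), "zero variance")
})
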