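test_that("causal_dag validates structure", {
  d <- causal_dag(rbind(c("X", "Y"), c("Y", "Z")), "chain")
  expect_equal(d$order, c("X", "Y", "Z"))
  expect_error(causal_dag(rbind(c("X", "Y"), c("Y", "X"))), "cyclic")
  expect_error(causal_dag(rbind(c("X", "X"))), "self-loop")
  expect_error(causal_dag(rbind(c("X", "Y"), c("X", "Y"))), "duplicate")
  expect_error(causal_dag(rbind(c("X", "Y")), nodes = c("X", "X", "Y")),
               "duplicate node")
})

test_that("basis sets match hand enumeration on canonical graphs", {
  chain <- causal_dag(rbind(c("X", "Y"), c("Y", "Z")), "chain")
  bs <- basis_set(chain)
  expect_length(bs, 1)
  expect_equal(bs[[1]], list(x = "X", y = "Z", cond = "Y"))

  full3 <- causal_dag(rbind(c("X", "Y"), c("X", "Z"), c("Y", "Z")))
  expect_length(basis_set(full3), 0)

  collider <- causal_dag(rbind(c("X", "Z"), c("Y", "Z")))
  bsc <- basis_set(collider)
  expect_length(bsc, 1)
  expect_setequal(c(bsc[[1]]$x, bsc[[1]]$y), c("X", "Y"))
  expect_length(bsc[[1]]$cond, 0)
})

test_that("every basis claim is d-separated per the brute-force oracle", {
  dags <- c(build_candidate_set(),
            list(causal_dag(rbind(c("X", "Y"), c("Y", "Z")), "chain"),
                 causal_dag(rbind(c("X", "Z"), c("Y", "Z")), "collider")))
  for (d in dags) {
    bs <- basis_set(d)
    # one claim per nonadjacent pair
    n_pairs <- choose(length(d$nodes), 2) - nrow(d$edges)
    expect_length(bs, n_pairs)
    for (cl in bs) {
      expect_true(dsep_oracle(d, cl$x, cl$y, cl$cond),
                  label = paste(d$name, cl$x, "_||_", cl$y, "|",
                                paste(cl$cond, collapse = ",")))
    }
  }
})

test_that("claim p-values are uniform under the null and tiny under dependence", {
  set.seed(71)
  n <- 500
  star <- ape::stree(n, "star"); star$edge.length <- rep(1, n)
  star$tip.label <- paste0("t", seq_len(n))
  cv <- precompute_eigen(shared_path_covariance(star))
  claim <- list(x = "X", y = "Y", cond = "Z")
  ps <- replicate(200, {
    Z <- rnorm(n)
    fr <- data.frame(X = 0.6 * Z + rnorm(n), Y = 0.6 * Z + rnorm(n),
                     Z = Z, row.names = star$tip.label)
    as.numeric(test_claim(claim, fr, cv, estimate_lambda = FALSE,
                          lambda = 0))
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)

  X <- rnorm(n)
  fr2 <- data.frame(X = X, Y = X, row.names = star$tip.label)
  p2 <- test_claim(list(x = "X", y = "Y", cond = character(0)), fr2, cv,
                   estimate_lambda = FALSE, lambda = 0)
  expect_lt(as.numeric(p2), 1e-10)
  expect_error(test_claim(list(x = "A", y = "B", cond = character(0)),
                          fr2, cv), "absent")
})

test_that("fishers_c matches the closed form and is monotone", {
  fc <- fishers_c(c(0.5, 0.5))
  expect_equal(fc$C, -2 * 2 * log(0.5), tolerance = 1e-12)
  expect_equal(fc$C, 2.772589, tolerance = 1e-6)
  expect_equal(fc$df, 4L)
  expect_equal(fc$p, pchisq(2.772589, 4, lower.tail = FALSE),
               tolerance = 1e-6)
  expect_equal(fc$p, 0.5965736, tolerance = 1e-6)

  fc0 <- fishers_c(numeric(0))
  expect_equal(fc0$C, 0); expect_equal(fc0$df, 0L); expect_equal(fc0$p, 1)
  expect_true(fc0$saturated)
  fc1 <- fishers_c(1)
  expect_equal(fc1$C, 0); expect_equal(fc1$df, 2L); expect_equal(fc1$p, 1)
  expect_error(fishers_c(c(0.5, 0)), "floor")
  expect_error(fishers_c(c(0.5, 1.2)), "\\(0, 1\\]")
  # monotone: decreasing any p increases C
  expect_gt(fishers_c(c(0.2, 0.5))$C, fishers_c(c(0.3, 0.5))$C)
})

test_that("cicc applies the small-sample correction", {
  expect_equal(cicc(0, 3, 10), 10)
  expect_equal(cicc(5, 0, 30), 5)
  expect_equal(cicc(2, 4, 21), 12.5)
  expect_error(cicc(1, 9, 10), "too rich")
})

test_that("rank_and_average weights and filters models correctly", {
  mk <- function(name, C, q, n, p, edges = NULL) {
    co <- if (is.null(edges)) {
      data.frame(from = character(0), to = character(0),
                 estimate = numeric(0), se = numeric(0),
                 lower = numeric(0), upper = numeric(0))
    } else edges
    structure(list(model = structure(list(name = name),
                                     class = "causal_dag"),
                   C = C, df = 2, p = p, q = q, n = n,
                   CICc = cicc(C, q, n), saturated = FALSE,
                   coefficients = co),
              class = "path_model_fit")
  }
  e1 <- data.frame(from = "A", to = "B", estimate = 1, se = 0.1,
                   lower = 0.8, upper = 1.2)
  e2 <- data.frame(from = "A", to = "B", estimate = 3, se = 0.1,
                   lower = 2.8, upper = 3.2)

  # single passing model gets weight 1
  out1 <- rank_and_average(list(mk("a", 1, 2, 50, 0.6, e1)))
  expect_equal(out1$table$weight, 1)
  expect_equal(out1$coefficients$estimate, 1)

  # equal CICc: symmetric weights and full-average of coefficients
  out2 <- rank_and_average(list(mk("a", 1, 2, 50, 0.6, e1),
                                mk("b", 1, 2, 50, 0.6, e2)))
  expect_equal(out2$table$weight, c(0.5, 0.5))
  expect_equal(out2$coefficients$estimate, 2)

  # deltas {0, 1, 3}: third excluded, weights prop to {1, e^-0.5}
  fits3 <- list(mk("a", 1, 2, 50, 0.6, e1),
                mk("b", 2, 2, 50, 0.5, e2),
                mk("c", 4, 2, 50, 0.4, e1))
  out3 <- rank_and_average(fits3)
  w <- c(1, exp(-0.5)); w <- w / sum(w)
  expect_equal(out3$table$weight[1:2], w, tolerance = 1e-12)
  expect_equal(out3$table$weight[3], 0)
  expect_equal(sum(out3$table$weight), 1)
  # invariant to input order
  out3r <- rank_and_average(rev(fits3))
  expect_equal(sort(out3r$table$weight), sort(out3$table$weight))

  # failing models never rank; all-failing errors
  expect_error(rank_and_average(list(mk("a", 50, 2, 50, 0.001, e1))),
               "no model consistent")
  outp <- rank_and_average(list(mk("a", 1, 2, 50, 0.6, e1),
                                mk("bad", 60, 2, 50, 0.01, e2)))
  expect_equal(outp$table$weight[outp$table$name == "bad"], 0)
})

test_that("the default candidate set is ten distinct DAGs with testable bases", {
  dags <- build_candidate_set()
  expect_length(dags, 10)
  sigs <- vapply(dags, function(d)
    paste(sort(paste(d$edges[, 1], d$edges[, 2])), collapse = ";"),
    character(1))
  expect_equal(anyDuplicated(sigs), 0L)
  for (d in dags) {
    expect_setequal(d$nodes, c("Ta", "Tb", "BMR", "NM", "body", "brain"))
    expect_gt(length(basis_set(d)), 0)
  }
  # a cyclic candidate file is rejected
  bad <- tempfile(fileext = ".json")
  writeLines('[{"name":"cyc","edges":[["A","B"],["B","A"]]}]', bad)
  expect_error(build_candidate_set(bad), "cyclic")
  dup <- tempfile(fileext = ".json")
  writeLines(paste0('[{"name":"a","edges":[["A","B"]]},',
                    '{"name":"b","edges":[["A","B"]]}]'), dup)
  expect_error(build_candidate_set(dup), "duplicate DAGs")
})

test_that("path model fitting ties claims, C and coefficients together", {
  set.seed(19)
  tr <- rand_tree(150, height = 100)
  cv <- precompute_eigen(shared_path_covariance(tr))
  gen <- causal_dag(rbind(c("X", "Y"), c("Y", "Z")), "chain")
  dat <- simulate_path_data(gen, c("X->Y" = 0.7, "Y->Z" = 0.7), cv,
                            lambda = 0.8, seed = 4)
  fit <- fit_path_model(gen, dat, cv)
  expect_equal(fit$df, 2L)
  expect_gt(fit$p, 0.001)
  expect_equal(fit$q, 2 + 3)
  expect_equal(nrow(fit$coefficients), 2)
  expect_equal(fit$CICc, cicc(fit$C, 5, 150))
  # the wrong model (reversed chain misses the X-Z dependence) fails C
  wrong <- causal_dag(rbind(c("X", "Y")), "missing", nodes = c("X", "Y", "Z"))
  fitw <- fit_path_model(wrong, dat, cv)
  expect_lt(fitw$p, 0.05)
})
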