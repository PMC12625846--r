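# Phylogenetic path analysis: candidate causal DAGs, d-separation basis
# sets, per-claim PGLS tests, Fisher's C, CICc ranking and CICc-weight
# model averaging.

#' Construct a causal DAG over named traits
#'
#' @param edges Two-column character matrix (or list of length-2 vectors)
#'   of directed `from -> to` pairs.
#' @param name Model label.
#' @param nodes Optional node set; defaults to the nodes appearing in
#'   `edges`. Must be unique.
#' @return Object of class `causal_dag` with `name`, `nodes`, `edges`,
#'   `parents` (named list) and a topological order.
#' @export
causal_dag <- function(edges, name = "model", nodes = NULL) {
  if (is.list(edges)) edges <- do.call(rbind, edges)
  edges <- matrix(as.character(edges), ncol = 2,
                  dimnames = list(NULL, c("from", "to")))
  if (is.null(nodes)) nodes <- unique(c(edges))
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node names")
  if (!all(c(edges) %in% nodes)) {
    stop("edges reference unknown nodes: ",
         paste(setdiff(c(edges), nodes), collapse = ", "))
  }
  if (anyDuplicated(paste(edges[, 1], edges[, 2]))) {
    stop("duplicate edges in DAG")
  }
  if (any(edges[, 1] == edges[, 2])) stop("self-loop edges are not allowed")
  ord <- topological_order(nodes, edges)
  parents <- lapply(setNames(nodes, nodes), function(v) {
    edges[edges[, 2] == v, 1]
  })
  structure(list(name = name, nodes = nodes, edges = edges,
                 parents = parents, order = ord),
            class = "causal_dag")
}

# Kahn's algorithm; errors on cycles
topological_order <- function(nodes, edges) {
  indeg <- setNames(integer(length(nodes)), nodes)
  for (v in edges[, 2]) indeg[v] <- indeg[v] + 1L
  queue <- sort(names(indeg)[indeg == 0L])  # lexicographic tie-break
  ord <- character(0)
  indeg_w <- indeg
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    ord <- c(ord, v)
    kids <- edges[edges[, 1] == v, 2]
    for (k in kids) {
      indeg_w[k] <- indeg_w[k] - 1L
      if (indeg_w[k] == 0L) queue <- sort(c(queue, k))
    }
  }
  if (length(ord) != length(nodes)) {
    stop("graph is cyclic: no topological order exists")
  }
  ord
}

#' @export
print.causal_dag <- function(x, ...) {
  cat("Causal DAG '", x$name, "' (", length(x$nodes), " nodes, ",
      nrow(x$edges), " edges)\n", sep = "")
  if (nrow(x$edges)) {
    cat(paste0("  ", x$edges[, 1], " -> ", x$edges[, 2]), sep = "\n")
  }
  invisible(x)
}

#' d-separation basis set of a DAG
#'
#' The minimal independence basis used in directed-separation path
#' analysis: one claim per nonadjacent node pair, conditioned on the union
#' of both nodes' parents. Within each pair the regression response is the
#' node later in topological order, so the claim is testable as the
#' partial coefficient of the earlier node. Claims are ordered
#' lexicographically by node names.
#'
#' @param dag A `causal_dag`.
#' @return List of claims, each `list(x, y, cond)` with `x` the tested
#'   predictor, `y` the response and `cond` the conditioning set.
#' @export
basis_set <- function(dag) {
  stopifnot(inherits(dag, "causal_dag"))
  nodes <- dag$nodes
  adj <- paste(dag$edges[, 1], dag$edges[, 2])
  adj <- c(adj, paste(dag$edges[, 2], dag$edges[, 1]))
  pos <- setNames(seq_along(dag$order), dag$order)
  claims <- list()
  for (i in seq_along(nodes)) {
    for (j in seq_along(nodes)) {
      if (i >= j) next
      a <- nodes[i]; b <- nodes[j]
      if (paste(a, b) %in% adj) next
      # response = later node in the causal (topological) order
      if (pos[a] <= pos[b]) { x <- a; y <- b } else { x <- b; y <- a }
      cond <- setdiff(union(dag$parents[[a]], dag$parents[[b]]), c(a, b))
      claims[[length(claims) + 1L]] <-
        list(x = x, y = y, cond = sort(cond))
    }
  }
  key <- vapply(claims, function(cl) paste(sort(c(cl$x, cl$y)),
                                           collapse = " "), character(1))
  claims[order(key)]
}

#' Test one d-separation claim with PGLS
#'
#' Fits a PGLS of the claim's response on the tested variable plus the
#' conditioning set and returns the two-sided p-value of the tested
#' variable's coefficient (t distribution with n - p degrees of freedom).
#'
#' @param claim A claim from [basis_set()].
#' @param frame Data frame of (transformed) trait columns.
#' @param cov Phylogenetic covariance aligned to `frame` rows.
#' @param ... Passed to [fit_pgls()] (e.g. `estimate_lambda`, `method`).
#' @return The p-value (also carries the fit as attribute `"fit"`).
#' @export
test_claim <- function(claim, frame, cov, ...) {
  vars <- c(claim$y, claim$x, claim$cond)
  if (!all(vars %in% names(frame))) {
    stop("claim variables absent from frame: ",
         paste(setdiff(vars, names(frame)), collapse = ", "))
  }
  X <- cbind(`(Intercept)` = 1,
             as.matrix(frame[, c(claim$x, claim$cond), drop = FALSE]))
  fit <- fit_pgls(frame[[claim$y]], X, cov, ...)
  p <- unname(fit$p_value[claim$x])
  attr(p, "fit") <- fit
  p
}

#' Fisher's C statistic
#'
#' C = -2 * sum(log p) over a model's independence-claim p-values;
#' chi-squared with 2k degrees of freedom under the causal model.
#'
#' @param p_values Numeric vector of p-values in (0, 1\]. An empty vector
#'   (saturated model) returns C = 0, df = 0, p = 1, flagged.
#' @return List with `C`, `df`, `p` (and `saturated` flag).
#' @export
fishers_c <- function(p_values) {
  p_values <- as.numeric(p_values)
  if (length(p_values) == 0) {
    return(list(C = 0, df = 0L, p = 1, saturated = TRUE))
  }
  if (any(!is.finite(p_values)) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  if (any(p_values <= 0)) {
    stop("p-value of 0 encountered: log diverges; floor p-values upstream")
  }
  C <- -2 * sum(log(p_values))
  df <- 2L * length(p_values)
  list(C = C, df = df, p = pchisq(C, df, lower.tail = FALSE),
       saturated = FALSE)
}

#' C-statistic information criterion (small-sample corrected)
#'
#' CICc = C + 2 * q * n / (n - 1 - q), with q the model's parameter count
#' (edges + nodes, each node contributing its residual variance).
#'
#' @param C Fisher's C.
#' @param q Parameter count.
#' @param n Sample size; requires n - 1 - q > 0.
#' @return CICc value.
#' @export
cicc <- function(C, q, n) {
  if (n - 1 - q <= 0) {
    stop("model too rich for sample: n - 1 - q = ", n - 1 - q)
  }
  C + 2 * q * n / (n - 1 - q)
}

#' Fit a single path model
#'
#' Evaluates every basis-set claim with PGLS, combines p-values into
#' Fisher's C and CICc, and estimates the path coefficients by PGLS of
#' each child on its parents.
#'
#' @param dag A `causal_dag`.
#' @param frame Data frame of trait columns (already transformed/scaled).
#' @param cov Phylogenetic covariance aligned to `frame`.
#' @param ... Passed to [fit_pgls()].
#' @return Object of class `path_model_fit`: `model`, `C`, `df`, `p`,
#'   `q`, `n`, `CICc`, `claims` (data frame) and `coefficients` (one row
#'   per edge with estimate, SE and 95% CI).
#' @export
fit_path_model <- function(dag, frame, cov, ...) {
  stopifnot(inherits(dag, "causal_dag"))
  claims <- basis_set(dag)
  pvals <- vapply(claims, function(cl) {
    as.numeric(test_claim(cl, frame, cov, ...))
  }, numeric(1))
  fc <- fishers_c(pvals)
  n <- nrow(frame)
  q <- nrow(dag$edges) + length(dag$nodes)
  claim_df <- if (length(claims)) {
    data.frame(x = vapply(claims, `[[`, "", "x"),
               y = vapply(claims, `[[`, "", "y"),
               cond = vapply(claims, function(cl)
                 paste(cl$cond, collapse = ","), ""),
               p = pvals, stringsAsFactors = FALSE)
  } else {
    data.frame(x = character(0), y = character(0), cond = character(0),
               p = numeric(0))
  }
  coefs <- path_coefficients(dag, frame, cov, ...)
  structure(list(model = dag, C = fc$C, df = fc$df, p = fc$p,
                 q = q, n = n, CICc = cicc(fc$C, q, n),
                 saturated = fc$saturated,
                 claims = claim_df, coefficients = coefs),
            class = "path_model_fit")
}

path_coefficients <- function(dag, frame, cov, ...) {
  rows <- list()
  for (v in dag$nodes) {
    pa <- dag$parents[[v]]
    if (!length(pa)) next
    X <- cbind(`(Intercept)` = 1, as.matrix(frame[, pa, drop = FALSE]))
    fit <- fit_pgls(frame[[v]], X, cov, ...)
    for (p_ in pa) {
      est <- unname(fit$coefficients[p_])
      se <- unname(fit$se[p_])
      rows[[length(rows) + 1L]] <- data.frame(
        from = p_, to = v, estimate = est, se = se,
        lower = est - qnorm(0.975) * se,
        upper = est + qnorm(0.975) * se, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(from = character(0), to = character(0),
                      estimate = numeric(0), se = numeric(0),
                      lower = numeric(0), upper = numeric(0)))
  }
  do.call(rbind, rows)
}

#' @export
print.path_model_fit <- function(x, ...) {
  cat(sprintf("Path model '%s': C = %.3f, df = %d, p = %.4f, q = %d, n = %d, CICc = %.3f\n",
              x$model$name, x$C, x$df, x$p, x$q, x$n, x$CICc))
  invisible(x)
}

#' Rank path models by CICc and average the supported set
#'
#' Restricts ranking to models consistent with the data (Fisher's C test
#' p > `alpha`), computes Delta-CICc against the best passing model, and
#' averages path coefficients over models with Delta < `delta_max` using
#' CICc weights w_i proportional to exp(-Delta_i / 2). By default the
#' average is "full": an edge absent from an included model contributes 0
#' to estimate and CI bounds (set `full = FALSE` for conditional
#' averaging over only the models containing each edge).
#'
#' @param fits List of `path_model_fit` objects.
#' @param alpha C-test passing threshold (default 0.05).
#' @param delta_max Delta-CICc inclusion threshold (default 2).
#' @param full Full (default) vs conditional averaging.
#' @return Object of class `averaged_paths`: `table` (one row per model:
#'   C, df, p, q, n, CICc, delta, weight, included) and `coefficients`
#'   (averaged estimate with 95% CI per edge).
#' @export
rank_and_average <- function(fits, alpha = 0.05, delta_max = 2,
                             full = TRUE) {
  stopifnot(length(fits) >= 1,
            all(vapply(fits, inherits, logical(1), "path_model_fit")))
  tab <- do.call(rbind, lapply(fits, function(f) {
    data.frame(name = f$model$name, C = f$C, df = f$df, p = f$p, q = f$q,
               n = f$n, CICc = f$CICc, stringsAsFactors = FALSE)
  }))
  pass <- tab$p > alpha
  if (!any(pass)) stop("no model consistent with data (all C-test p <= ",
                       alpha, ")")
  best <- min(tab$CICc[pass])
  tab$delta <- ifelse(pass, tab$CICc - best, NA_real_)
  incl <- pass & tab$delta < delta_max
  w <- exp(-tab$delta[incl] / 2)
  w <- w / sum(w)
  tab$weight <- 0
  tab$weight[incl] <- w
  tab$included <- incl
  tab <- tab[order(!pass, tab$CICc), ]
  rownames(tab) <- NULL

  inc_fits <- fits[incl]
  all_edges <- unique(do.call(rbind, lapply(inc_fits, function(f)
    f$coefficients[, c("from", "to")])))
  avg <- do.call(rbind, lapply(seq_len(nrow(all_edges)), function(i) {
    fr <- all_edges$from[i]; to <- all_edges$to[i]
    est <- lo <- up <- hasit <- numeric(length(inc_fits))
    for (k in seq_along(inc_fits)) {
      cf <- inc_fits[[k]]$coefficients
      hit <- cf$from == fr & cf$to == to
      if (any(hit)) {
        est[k] <- cf$estimate[hit]; lo[k] <- cf$lower[hit]
        up[k] <- cf$upper[hit]; hasit[k] <- 1
      }
    }
    wk <- w
    if (!full) {
      if (!any(hasit > 0)) return(NULL)
      wk <- w * hasit
      wk <- wk / sum(wk)
    }
    data.frame(from = fr, to = to,
               estimate = sum(wk * est), lower = sum(wk * lo),
               upper = sum(wk * up), stringsAsFactors = FALSE)
  }))
  structure(list(table = tab, coefficients = avg,
                 alpha = alpha, delta_max = delta_max, full = full),
            class = "averaged_paths")
}

#' @export
print.averaged_paths <- function(x, ...) {
  cat("Path-model ranking (C-test alpha =", x$alpha, ", Delta-CICc <",
      x$delta_max, "averaged):\n")
  print(transform(x$table, C = round(C, 3), p = round(p, 4),
                  CICc = round(CICc, 3), delta = round(delta, 3),
                  weight = round(weight, 3)))
  cat("\nAveraged path coefficients:\n")
  print(transform(x$coefficients, estimate = round(estimate, 4),
                  lower = round(lower, 4), upper = round(upper, 4)))
  invisible(x)
}

#' Build the candidate DAG set
#'
#' Reads candidate causal models from JSON
#' (`[{"name": ..., "edges": [["Ta","Tb"], ...]}, ...]`). Without a path,
#' returns the packaged default family of 10 models over the six traits
#' (ambient temperature `Ta`, body temperature `Tb`, residual `BMR`,
#' residual newborn size `NM`, adult `body` mass, residual `brain` size):
#' a common backbone (`body -> NM`, `NM -> brain`, `Ta -> BMR`) crossed
#' with the orientation of the temperature-metabolism link
#' (`Tb -> BMR` plus `Ta -> Tb`, versus `BMR -> Tb`) and five
#' direct-to-brain parent sets drawn from \{Ta, Tb, BMR\}. This default is
#' a documented, replaceable stand-in for an unpublished candidate set.
#'
#' @param path Optional JSON file of candidate models.
#' @return List of `causal_dag` objects (all distinct and acyclic).
#' @export
build_candidate_set <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "candidate_dags.json",
                        package = "vertbrain", mustWork = TRUE)
  }
  spec <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  dags <- lapply(spec, function(m) {
    causal_dag(lapply(m$edges, unlist), name = m$name,
               nodes = if (!is.null(m$nodes)) unlist(m$nodes) else NULL)
  })
  sig <- vapply(dags, function(d) {
    paste(sort(paste(d$edges[, 1], d$edges[, 2])), collapse = ";")
  }, character(1))
  if (anyDuplicated(sig)) {
    stop("duplicate DAGs in candidate set: ",
         paste(vapply(dags[duplicated(sig)], `[[`, "", "name"),
               collapse = ", "))
  }
  dags
}
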