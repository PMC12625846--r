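# Independent oracles used across the suite.

# Generalized least squares by explicit normal equations (generic solver,
# no eigen tricks): beta = (X' V^-1 X)^-1 X' V^-1 y.
gls_oracle <- function(y, X, V) {
  Vi <- solve(V)
  XtVi <- t(X) %*% Vi
  A <- solve(XtVi %*% X)
  beta <- drop(A %*% (XtVi %*% y))
  n <- length(y); p <- ncol(X)
  r <- y - drop(X %*% beta)
  sigma2 <- drop(t(r) %*% Vi %*% r) / (n - p)
  list(beta = beta, se = sqrt(diag(A * sigma2)), sigma2 = sigma2)
}

# Brute-force d-separation check via the moralized ancestral graph:
# x and y are d-separated by cond iff they are disconnected in the
# moralization of the subgraph induced by the ancestors of {x, y} U cond,
# after deleting cond.
dsep_oracle <- function(dag, x, y, cond) {
  parents <- dag$parents
  anc <- unique(c(x, y, cond))
  repeat {
    more <- unique(c(anc, unlist(parents[anc])))
    if (length(more) == length(anc)) break
    anc <- more
  }
  # adjacency of the moral graph on `anc`
  adj <- list()
  add_edge <- function(a, b) {
    adj[[a]] <<- union(adj[[a]], b)
    adj[[b]] <<- union(adj[[b]], a)
  }
  for (v in anc) adj[[v]] <- character(0)
  for (v in anc) {
    pa <- intersect(parents[[v]], anc)
    for (p_ in pa) add_edge(p_, v)
    if (length(pa) > 1) {
      for (i in seq_len(length(pa) - 1)) {
        for (j in (i + 1):length(pa)) add_edge(pa[i], pa[j])
      }
    }
  }
  # BFS from x avoiding cond
  blocked <- cond
  seen <- x
  queue <- x
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in setdiff(adj[[v]], c(seen, blocked))) {
      if (w == y) return(FALSE)  # connected => not separated
      seen <- c(seen, w)
      queue <- c(queue, w)
    }
  }
  TRUE
}

# upper Cholesky factor tolerant of semidefinite matrices
chol_psd_test <- function(M) {
  tryCatch(chol(M), error = function(e) {
    eg <- eigen(M, symmetric = TRUE)
    t(eg$vectors %*% (t(eg$vectors) * sqrt(pmax(eg$values, 0))))
  })
}

# random ultrametric tree with prefixed labels, scaled to a given height
rand_tree <- function(n, height = 100, prefix = "t", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n, birth = 1, death = 0)
  tr$tip.label <- paste0(prefix, seq_len(n))
  tr$edge.length <- tr$edge.length * height / vertbrain::tree_height(tr)
  tr
}
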