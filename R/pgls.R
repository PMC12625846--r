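# Phylogenetic generalized least squares with Pagel's-lambda estimation.
#
# The covariance is normalized to correlation form before lambda profiling
# (sigma^2 absorbs the scale), so on an ultrametric tree the working
# covariance is V(lambda) = lambda * C + (1 - lambda) * I with unit
# diagonal, which shares the eigenvectors of C. All fits therefore reduce
# to weighted least squares in the eigenbasis of C, making the lambda
# profile cheap.

#' Fit a phylogenetic generalized least squares model
#'
#' Estimates beta-hat = (X' V^-1 X)^-1 X' V^-1 y with V the Pagel's-lambda
#' transform of the phylogenetic correlation matrix, scaled by sigma^2.
#' When `estimate_lambda` is `TRUE`, lambda maximizes the restricted
#' likelihood (default) or the full likelihood over \[0, 1\] by bounded
#' scalar search with endpoint checks.
#'
#' @param y Response vector, aligned to `cov`'s taxa order.
#' @param X Design matrix (including intercept column), same row order.
#' @param cov A [shared_path_covariance()] result or a symmetric matrix.
#' @param estimate_lambda Estimate lambda (`TRUE`) or fix it at `lambda`.
#' @param lambda Fixed lambda used when `estimate_lambda = FALSE`.
#' @param method `"REML"` (default) or `"ML"` for the lambda profile.
#' @return Object of class `pgls_fit`: coefficients, standard errors,
#'   t/p-values, `lambda`, `logLik`, `sigma2`, `n`, `df_residual`, `vcov`.
#' @export
fit_pgls <- function(y, X, cov, estimate_lambda = TRUE, lambda = 1,
                     method = c("REML", "ML")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (is.null(colnames(X))) {
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(ncol(X) - 1)))[
      seq_len(ncol(X))]
  }
  n <- length(y)
  if (nrow(X) != n) stop("y and X must have the same number of rows")
  if (n <= ncol(X)) {
    stop("n (", n, ") must exceed the number of design columns (",
         ncol(X), ")")
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("singular design matrix; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  eg <- cov_eigen(cov, n)
  yt <- crossprod(eg$vectors, y)
  Xt <- crossprod(eg$vectors, X)

  if (estimate_lambda) {
    obj <- function(l) pgls_negll(l, yt, Xt, eg$values, method)
    opt <- optimize(obj, interval = c(0, 1), tol = 1e-6)
    cand <- c(opt$minimum, 0, 1)
    vals <- c(opt$objective, obj(0), obj(1))
    lambda <- cand[which.min(vals)]
  } else {
    if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  }
  pgls_finish(lambda, y, X, yt, Xt, eg, method)
}

# eigen-decomposition of the correlation-form covariance; reused when the
# phylo_cov carries a cache from precompute_eigen()
cov_eigen <- function(cov, n) {
  if (inherits(cov, "phylo_cov") && !is.null(cov$eigen)) {
    if (length(cov$eigen$values) != n) {
      stop("covariance dimension does not match data")
    }
    return(cov$eigen)
  }
  M <- cov_matrix(cov)
  if (nrow(M) != n) stop("covariance dimension does not match data")
  d0 <- diag(M)
  if (any(d0 <= 0)) stop("covariance has non-positive diagonal")
  C <- M / sqrt(d0 %o% d0)  # correlation form; sigma^2 absorbs scale
  eg <- eigen(C, symmetric = TRUE)
  if (min(eg$values) < -1e-8 * max(eg$values)) {
    stop("covariance is not positive semi-definite (min eigenvalue ",
         format(min(eg$values)), ")")
  }
  eg$values <- pmax(eg$values, 0)
  eg
}

#' Cache the eigendecomposition of a phylogenetic covariance
#'
#' Fitting functions eigendecompose the correlation form of the
#' covariance; for repeated fits against the same matrix (path analysis
#' tests many claims) precomputing once avoids an O(n^3) cost per fit.
#'
#' @param cov A `phylo_cov`.
#' @return The same object with an `eigen` cache attached.
#' @export
precompute_eigen <- function(cov) {
  stopifnot(inherits(cov, "phylo_cov"))
  bare <- cov
  bare$eigen <- NULL
  cov$eigen <- cov_eigen(bare, nrow(cov$matrix))
  cov
}

# weights of V(lambda) in the eigenbasis of C (unit-diagonal C)
lambda_weights <- function(lambda, d) lambda * d + (1 - lambda)

# negative (restricted) log-likelihood profiled over beta and sigma^2
pgls_negll <- function(lambda, yt, Xt, d, method) {
  w <- lambda_weights(lambda, d)
  if (any(w <= 0)) return(Inf)
  n <- length(yt); p <- ncol(Xt)
  Xw <- Xt / sqrt(w); yw <- yt / sqrt(w)
  XtX <- crossprod(Xw)
  beta <- tryCatch(solve(XtX, crossprod(Xw, yw)),
                   error = function(e) NULL)
  if (is.null(beta)) return(Inf)
  rss <- sum((yw - Xw %*% beta)^2)
  if (method == "ML") {
    s2 <- rss / n
    0.5 * (n * log(2 * pi) + n * log(s2) + sum(log(w)) + n)
  } else {
    s2 <- rss / (n - p)
    0.5 * ((n - p) * log(2 * pi) + (n - p) * log(s2) + sum(log(w)) +
             determinant(XtX, logarithm = TRUE)$modulus[1] + (n - p))
  }
}

pgls_finish <- function(lambda, y, X, yt, Xt, eg, method) {
  d <- eg$values
  w <- lambda_weights(lambda, d)
  n <- length(yt); p <- ncol(Xt)
  Xw <- Xt / sqrt(w); yw <- yt / sqrt(w)
  XtX <- crossprod(Xw)
  XtXi <- solve(XtX)
  beta <- drop(XtXi %*% crossprod(Xw, yw))
  names(beta) <- colnames(X)
  rss <- sum((yw - Xw %*% beta)^2)
  sigma2 <- rss / (n - p)
  vc <- XtXi * sigma2
  se <- sqrt(diag(vc))
  tval <- beta / se
  pval <- 2 * pt(-abs(tval), df = n - p)
  ll <- -pgls_negll(lambda, yt, Xt, d, method)
  structure(list(coefficients = beta, se = se, t_value = tval,
                 p_value = pval, lambda = lambda, logLik = ll,
                 sigma2 = sigma2, n = n, df_residual = n - p,
                 vcov = vc, method = method,
                 fitted = drop(X %*% beta), residuals = y - drop(X %*% beta)),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("PGLS fit (", x$method, " lambda = ", format(x$lambda, digits = 4),
      ", n = ", x$n, ", logLik = ", format(x$logLik, digits = 6), ")\n",
      sep = "")
  tab <- cbind(Estimate = x$coefficients, `Std. Error` = x$se,
               `t value` = x$t_value, `p value` = x$p_value)
  print(round(tab, 5))
  invisible(x)
}

#' Predict from a PGLS fit
#'
#' @param object A `pgls_fit`.
#' @param X_new Design matrix with the same columns as the training design.
#' @param ... Ignored.
#' @return Numeric vector `X_new %*% coef`.
#' @export
predict_pgls <- function(object, X_new, ...) {
  stopifnot(inherits(object, "pgls_fit"))
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(object$coefficients)) {
    stop("X_new has ", ncol(X_new), " columns; fit has ",
         length(object$coefficients), " coefficients")
  }
  drop(X_new %*% object$coefficients)
}

#' @export
predict.pgls_fit <- function(object, X_new, ...) predict_pgls(object, X_new)

#' Serialize a PGLS fit as JSON
#'
#' @param fit A `pgls_fit`.
#' @param path Output path.
#' @export
write_pgls_json <- function(fit, path) {
  jsonlite::write_json(
    list(coefficients = as.list(fit$coefficients),
         se = as.list(setNames(fit$se, names(fit$coefficients))),
         lambda = fit$lambda, logLik = fit$logLik, sigma2 = fit$sigma2,
         n = fit$n, method = fit$method),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
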