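# Step 1: REML fit of the null animal model y = X beta + u + e,
# u ~ N(0, G sigma_u^2), e ~ N(0, I sigma_e^2). Each individual carries one
# record, so the incidence of the animal effect is the identity and
# V0 = G sigma_u^2 + I sigma_e^2. The fit profiles the total variance out
# of the restricted likelihood and searches over the heritability
# h2 = sigma_u^2 / (sigma_u^2 + sigma_e^2) on the eigenbasis of G, where
# every likelihood evaluation is O(n).

# Restricted log-likelihood at fixed h2, total variance profiled out.
# Works in the eigenbasis: ye = U'y, Xe = U'X, delta_i = h2 d_i + (1-h2).
reml_ll_rotated <- function(ye, Xe, d, h2, n, p, logdet_xtx) {
  delta <- h2 * d + (1 - h2)
  if (any(delta <= 0)) return(-Inf)
  XtHiX <- crossprod(Xe, Xe / delta)
  XtHiy <- crossprod(Xe, ye / delta)
  ch <- tryCatch(chol(XtHiX), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  beta <- backsolve(ch, forwardsolve(t(ch), XtHiy))
  r <- ye - Xe %*% beta
  q <- sum(r^2 / delta)
  s2 <- q / (n - p)
  -0.5 * ((n - p) * (log(2 * pi * s2) + 1) + sum(log(delta)) +
            2 * sum(log(diag(ch))) - logdet_xtx)
}

#' Profiled restricted log-likelihood of the null animal model
#'
#' Evaluates the restricted log-likelihood of
#' `y = X beta + u + e`, `u ~ N(0, G sigma_u^2)`, `e ~ N(0, I sigma_e^2)`,
#' at a fixed heritability `h2 = sigma_u^2 / (sigma_u^2 + sigma_e^2)`,
#' with the total variance `sigma_u^2 + sigma_e^2` profiled out at its
#' REML value. Evaluated through the eigendecomposition of `G`, so each
#' call is O(n) after an O(n^3) setup.
#'
#' @param y Numeric phenotype vector.
#' @param X Fixed-effect design matrix (default: intercept only).
#' @param G A [compute_grm()] result or a symmetric matrix.
#' @param h2 Heritability in `[0, 1)`.
#' @return The restricted log-likelihood (scalar).
#' @export
profile_loglik <- function(y, X = NULL, G, h2) {
  if (h2 < 0 || h2 >= 1) stop("h2 must lie in [0, 1)")
  g <- if (inherits(G, "grm")) G$g else as.matrix(G)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  X <- as.matrix(X)
  eg <- eigen(g, symmetric = TRUE)
  ye <- crossprod(eg$vectors, y)
  Xe <- crossprod(eg$vectors, X)
  logdet_xtx <- determinant(crossprod(X), logarithm = TRUE)$modulus
  reml_ll_rotated(ye, Xe, eg$values, h2, n, ncol(X),
                  as.numeric(logdet_xtx))
}

#' Fit the null animal model by REML
#'
#' Step 1 of the two-step scan: fits `y = X beta + u + e` with
#' `u ~ N(0, G sigma_u^2)` and `e ~ N(0, I sigma_e^2)` by restricted
#' maximum likelihood, and packages the spectral representation of the
#' null covariance `V0 = G sigma_u^2 + I sigma_e^2` so that `V0^{-1} v`
#' costs O(n^2) for any vector downstream.
#'
#' The optimiser scans `h2` over a grid on `[0, 0.99]` (step 0.01) and
#' refines the best grid cell by golden-section search to
#' `|delta h2| < 1e-6`. `converged` is `FALSE` when the optimum sits on
#' the boundary of the parameter space or the iteration cap is reached.
#'
#' @param y Numeric phenotype vector (finite).
#' @param X Fixed-effect design (default: intercept only). Must have full
#'   column rank.
#' @param G A [compute_grm()] result (or symmetric matrix) for the same
#'   individuals, in the same order as `y`.
#' @param max_iter Golden-section iteration cap (default 200).
#' @return Object of class `null_fit`: variance components `vc`
#'   (`sigma_u2`, `sigma_e2`, `h2`, `loglik`, `converged`, `n_iter`),
#'   GLS fixed-effect solutions `beta_hat`, the design `X`, residuals
#'   `y - X beta_hat`, the eigenpairs of `G` (`eigen$values`,
#'   `eigen$vectors`), individual `ids`, and `n`.
#' @export
fit_null <- function(y, X = NULL, G, max_iter = 200L) {
  if (!all(is.finite(y))) stop("phenotype vector contains non-finite values")
  g <- if (inherits(G, "grm")) G$g else as.matrix(G)
  ids <- if (inherits(G, "grm")) G$ids else rownames(g)
  n <- length(y)
  if (nrow(g) != n)
    stop("y has ", n, " records but G is ", nrow(g), " x ", ncol(g))
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  X <- as.matrix(X)
  p <- ncol(X)
  qr_x <- qr(X)
  if (qr_x$rank < p) {
    dep <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):p]]
    stop("fixed-effect design is rank deficient; collinear column(s): ",
         paste(dep, collapse = ", "))
  }

  eg <- eigen(g, symmetric = TRUE)
  ye <- crossprod(eg$vectors, y)
  Xe <- crossprod(eg$vectors, X)
  logdet_xtx <- as.numeric(determinant(crossprod(X), TRUE)$modulus)
  ll <- function(h2) reml_ll_rotated(ye, Xe, eg$values, h2, n, p, logdet_xtx)

  grid <- seq(0, 0.99, by = 0.01)
  vals <- vapply(grid, ll, 0)
  k <- which.max(vals)
  lo <- grid[max(k - 1L, 1L)]
  hi <- grid[min(k + 1L, length(grid))]

  # golden-section search on [lo, hi]
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- ll(x1); f2 <- ll(x2)
  iter <- 0L
  while (b - a > 1e-6 && iter < max_iter) {
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- ll(x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- ll(x1)
    }
    iter <- iter + 1L
  }
  h2_hat <- (a + b) / 2
  ll_hat <- ll(h2_hat)
  boundary <- h2_hat <= 1e-6 || h2_hat >= 0.99 - 1e-6
  converged <- (b - a <= 1e-6) && !boundary
  if (boundary && vals[k] >= ll_hat) { h2_hat <- grid[k]; ll_hat <- vals[k] }

  # GLS solutions and variance components at the optimum
  delta <- h2_hat * eg$values + (1 - h2_hat)
  XtHiX <- crossprod(Xe, Xe / delta)
  beta <- solve(XtHiX, crossprod(Xe, ye / delta))
  r_rot <- ye - Xe %*% beta
  s2 <- sum(r_rot^2 / delta) / (n - p)
  sigma_u2 <- h2_hat * s2
  sigma_e2 <- (1 - h2_hat) * s2
  beta_hat <- drop(beta)
  names(beta_hat) <- colnames(X)
  residuals <- drop(y - X %*% beta)

  structure(list(
    vc = list(sigma_u2 = sigma_u2, sigma_e2 = sigma_e2, h2 = h2_hat,
              loglik = ll_hat, converged = converged, n_iter = iter),
    beta_hat = beta_hat,
    X = X,
    residuals = residuals,
    eigen = list(values = eg$values, vectors = eg$vectors),
    ids = ids,
    n = n
  ), class = "null_fit")
}

#' @export
print.null_fit <- function(x, ...) {
  cat("null_fit (animal model, REML):\n")
  cat(sprintf("  sigma_u2 = %.4f  sigma_e2 = %.4f  h2 = %.4f\n",
              x$vc$sigma_u2, x$vc$sigma_e2, x$vc$h2))
  cat(sprintf("  restricted logLik = %.3f  converged = %s (%d iter)\n",
              x$vc$loglik, x$vc$converged, x$vc$n_iter))
  invisible(x)
}

#' Apply the inverse null covariance to a vector
#'
#' Computes `V0^{-1} v` with `V0 = G sigma_u2 + I sigma_e2` through the
#' stored eigendecomposition of `G`.
#'
#' @param nf A [fit_null()] result.
#' @param v Numeric vector (or matrix, column-wise) of length `nf$n`.
#' @return `V0^{-1} v`, same shape as `v`.
#' @export
v0_solve <- function(nf, v) {
  stopifnot(inherits(nf, "null_fit"))
  w <- nf$vc$sigma_u2 * nf$eigen$values + nf$vc$sigma_e2
  vm <- as.matrix(v)
  out <- nf$eigen$vectors %*% (crossprod(nf$eigen$vectors, vm) / w)
  if (is.matrix(v)) out else drop(out)
}

#' Null-fit summary as a list (for JSON/TSV export)
#'
#' @param nf A [fit_null()] result.
#' @param n_markers Optional marker count to record.
#' @return Named list of scalar summaries.
#' @export
null_fit_summary <- function(nf, n_markers = NA_integer_) {
  list(sigma_u2 = nf$vc$sigma_u2, sigma_e2 = nf$vc$sigma_e2,
       h2 = nf$vc$h2, loglik = nf$vc$loglik, n = nf$n,
       n_markers = n_markers, converged = nf$vc$converged)
}
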