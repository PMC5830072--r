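# Genomic control and Bonferroni multiple-testing correction.

#' Estimate the genomic-control inflation factor
#'
#' Under the null, the squared score statistics are chi-squared with one
#' degree of freedom; systematic inflation (from residual structure the
#' model missed) scales them by a factor lambda. The default estimator is
#' the classical median ratio `lambda = median(z^2) / qchisq(0.5, 1)`
#' (the chi-square(1) median is 0.4549). The `"regression"` alternative,
#' in the style of variance-inflation-factor estimators, regresses the
#' sorted `z^2` through the origin on the expected chi-square(1) order
#' statistics, trimmed to the lower 90% so tail signal does not drive
#' the slope.
#'
#' @param z_stats Numeric vector of z statistics (at least 2 finite
#'   values; fewer than 30 triggers a small-sample warning).
#' @param method `"median"` (default) or `"regression"`.
#' @return Object of class `gc_estimate`: `lambda`, `method`, `n_stats`.
#' @export
estimate_lambda <- function(z_stats, method = c("median", "regression")) {
  method <- match.arg(method)
  z <- z_stats[is.finite(z_stats)]
  n <- length(z)
  if (n < 2) stop("need at least 2 finite statistics to estimate lambda")
  if (n < 30)
    warning("only ", n, " statistics; lambda estimate will be unstable")
  if (length(unique(z)) == 1L)
    warning("all statistics identical; lambda estimate is degenerate")
  chi <- z^2
  lambda <- if (method == "median") {
    stats::median(chi) / stats::qchisq(0.5, df = 1)
  } else {
    obs <- sort(chi)
    expd <- stats::qchisq((seq_len(n) - 0.5) / n, df = 1)
    k <- max(2L, floor(0.9 * n))
    sum(obs[1:k] * expd[1:k]) / sum(expd[1:k]^2)
  }
  structure(list(lambda = lambda, method = method, n_stats = n),
            class = "gc_estimate")
}

#' @export
print.gc_estimate <- function(x, ...) {
  cat(sprintf("genomic control: lambda = %.4f (%s method, %d statistics)\n",
              x$lambda, x$method, x$n_stats))
  invisible(x)
}

#' Genomic-control-adjusted p-values
#'
#' Deflates the statistics by `sqrt(lambda)` when `lambda > 1` and
#' recomputes two-sided normal p-values: `p_gc = 2 Phi(-|z| / sqrt(lambda))`.
#' When `lambda <= 1` the raw p-values are returned unchanged (deflation
#' is not "corrected").
#'
#' @param z_stats Numeric vector of z statistics (`NA` propagates).
#' @param gc A [estimate_lambda()] result (or a bare lambda value).
#' @return Numeric vector of adjusted p-values.
#' @export
gc_adjust <- function(z_stats, gc) {
  lambda <- if (inherits(gc, "gc_estimate")) gc$lambda else as.numeric(gc)
  if (!is.finite(lambda)) stop("lambda must be finite")
  scale <- if (lambda > 1) sqrt(lambda) else 1
  2 * stats::pnorm(-abs(z_stats) / scale)
}

#' Bonferroni per-test significance threshold
#'
#' @param alpha Family-wise error rate in (0, 1).
#' @param m Number of tests (>= 1).
#' @return Per-test threshold `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (length(m) != 1 || is.na(m) || m < 1)
    stop("m must be a positive number of tests")
  alpha / m
}
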