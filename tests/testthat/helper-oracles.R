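# Independent dense-matrix oracles and fixture builders for the suite.
# Everything here deliberately uses explicit solve()/determinant() on the
# full covariance, never the package's spectral pathway.

# Restricted log-likelihood at fixed h2 with the total variance profiled
# out, computed from dense inverses and determinants of H = h2 G + (1-h2) I.
dense_reml_ll <- function(y, X, G, h2) {
  n <- length(y)
  p <- ncol(X)
  H <- h2 * G + (1 - h2) * diag(n)
  Hi <- solve(H)
  XtHiX <- crossprod(X, Hi %*% X)
  beta <- solve(XtHiX, crossprod(X, Hi %*% y))
  r <- y - X %*% beta
  q <- drop(crossprod(r, Hi %*% r))
  s2 <- q / (n - p)
  ld_H <- as.numeric(determinant(H, logarithm = TRUE)$modulus)
  ld_XtHiX <- as.numeric(determinant(XtHiX, logarithm = TRUE)$modulus)
  ld_XtX <- as.numeric(determinant(crossprod(X), logarithm = TRUE)$modulus)
  -0.5 * ((n - p) * (log(2 * pi * s2) + 1) + ld_H + ld_XtHiX - ld_XtX)
}

# The two-step statistic of a centred coded vector, from an explicitly
# inverted dense V0 = G sigma_u2 + I sigma_e2.
dense_two_step <- function(y, X, x_coded, G, sigma_u2, sigma_e2) {
  n <- length(y)
  V0 <- sigma_u2 * G + sigma_e2 * diag(n)
  Vi <- solve(V0)
  beta0 <- solve(crossprod(X, Vi %*% X), crossprod(X, Vi %*% y))
  r <- y - X %*% beta0
  xc <- x_coded - mean(x_coded)
  num <- drop(crossprod(xc, Vi %*% r))
  den <- drop(crossprod(xc, Vi %*% xc))
  list(beta = num / den, se = 1 / sqrt(den), z = num / sqrt(den))
}

# Wald z on the x coefficient from a joint dense GLS fit of y on [X, x]
# with known V0 (what the two-step statistic approximates).
dense_joint_wald <- function(y, X, x_coded, G, sigma_u2, sigma_e2) {
  n <- length(y)
  V0 <- sigma_u2 * G + sigma_e2 * diag(n)
  Vi <- solve(V0)
  C <- cbind(X, x_coded - mean(x_coded))
  CtViC <- crossprod(C, Vi %*% C)
  b <- solve(CtViC, crossprod(C, Vi %*% y))
  covb <- solve(CtViC)
  k <- ncol(C)
  b[k] / sqrt(covb[k, k])
}

# Random positive-definite relationship-like matrix with unit-scale diagonal.
rand_relmat <- function(n) {
  A <- matrix(stats::rnorm(n * (n + 5)), n, n + 5)
  G <- tcrossprod(A) / (n + 5)
  G / mean(diag(G))
}

# Random genotype_matrix fixture (optionally with missing calls and
# non-autosomal labels), for round-trip and QC tests.
rand_gm <- function(n, m, maf = c(0.1, 0.5), miss_rate = 0,
                    chr = NULL) {
  p <- stats::runif(m, maf[1], maf[2])
  dos <- sapply(p, function(pp) stats::rbinom(n, 2, pp))
  dos <- matrix(dos, n, m)
  if (miss_rate > 0)
    dos[stats::runif(n * m) < miss_rate] <- NA
  if (is.null(chr)) chr <- as.character(sample(1:29, m, replace = TRUE))
  markers <- data.frame(
    snp_id = sprintf("m%04d", seq_len(m)), chr = chr,
    pos = sort(sample(1e4:1e7, m)),
    allele_a = "A", allele_b = "B", stringsAsFactors = FALSE
  )
  genotype_matrix(dos, sprintf("ind%04d", seq_len(n)), markers)
}

# Printed genotype counts of the seven top markers (the study's published
# table), used as inputs for MAF arithmetic checks.
published_marker_counts <- function() {
  data.frame(
    marker = c("BTA-21730-no-rs", "Hapmap50123-BTA-83561", "BTB-00534589",
               "BTB-00682926", "Hapmap50918-BTA-23068",
               "Hapmap58840-rs29018856", "BTB-01301223"),
    n_AA = c(145, 17, 148, 103, 4095, 5644, 5073),
    n_AB = c(1870, 885, 1942, 1917, 2905, 1715, 2219),
    n_BB = c(5443, 6556, 5367, 5437, 458, 99, 166),
    maf_printed = c(0.145, 0.062, 0.150, 0.142, 0.256, 0.128, 0.171),
    stringsAsFactors = FALSE
  )
}
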