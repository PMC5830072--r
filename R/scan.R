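# Step 2: per-marker score tests against the frozen null covariance.

#' Score test of one coded marker against the null fit
#'
#' Tests a single coded design vector `x` with the two-step statistic
#' `z = x' V0^{-1} (y - X beta_hat) / sqrt(x' V0^{-1} x)`, where
#' `beta_hat` and `V0` are frozen from the step-1 null fit. The statistic
#' approximates the Wald test and is treated as standard normal, giving
#' the two-sided p-value `2 Phi(-|z|)`. Equivalently,
#' `beta = x' V0^{-1} r / (x' V0^{-1} x)` and `se = (x' V0^{-1} x)^{-1/2}`,
#' so `z = beta / se`.
#'
#' The coded vector is mean-centred before testing so the step-1
#' intercept absorbs the coding's baseline. A coded vector that is
#' (numerically) constant is untestable and yields `NA` statistics with
#' `untestable = TRUE` rather than an error.
#'
#' @param x_coded Numeric coded design vector (one value per individual,
#'   same order as the null fit).
#' @param nf A [fit_null()] result.
#' @return List: `beta`, `se`, `z`, `p_raw`, `untestable`.
#' @export
snp_test <- function(x_coded, nf) {
  stopifnot(inherits(nf, "null_fit"))
  if (length(x_coded) != nf$n)
    stop("coded vector length ", length(x_coded),
         " does not match the null fit (n = ", nf$n, ")")
  xc <- x_coded - mean(x_coded)
  w <- nf$vc$sigma_u2 * nf$eigen$values + nf$vc$sigma_e2
  a <- drop(crossprod(nf$eigen$vectors, xc))
  re <- drop(crossprod(nf$eigen$vectors, nf$residuals))
  den <- sum(a^2 / w)
  # floor scales with the marker's magnitude: catches constant codings
  if (den <= 1e-10 * max(1, sum(xc^2))) {
    return(list(beta = NA_real_, se = NA_real_, z = NA_real_,
                p_raw = NA_real_, untestable = TRUE))
  }
  num <- sum(a * re / w)
  beta <- num / den
  se <- 1 / sqrt(den)
  z <- beta / se
  list(beta = beta, se = se, z = z,
       p_raw = 2 * stats::pnorm(-abs(z)), untestable = FALSE)
}

#' Whole-genome scan under one or more coding models
#'
#' Runs the step-2 score test for every marker under each requested
#' coding. The additive coding is always computed alongside the requested
#' non-additive codings so each marker reports both a non-additive and an
#' additive p-value. Missing dosages are mean-imputed per marker before
#' coding. Per model, the genomic-control inflation factor is estimated
#' from the scan's own z statistics and adjusted p-values are attached.
#'
#' @param gm A [genotype_matrix()], already QC-filtered, with individuals
#'   in exactly the order of the null fit (checked against `nf$ids`).
#' @param y Numeric phenotype vector used in the null fit (retained for
#'   provenance; the test uses the stored null residuals).
#' @param nf A [fit_null()] result for the same individuals.
#' @param models Character vector of codings to scan (default: the three
#'   non-additive codings).
#' @param gc_method Genomic-control estimator, `"median"` or
#'   `"regression"` (see [estimate_lambda()]).
#' @return Object of class `scan_result`: `results` (one data frame row
#'   per marker per model: `snp_id`, `chr`, `pos`, `model`, `maf`,
#'   `n_AA`, `n_AB`, `n_BB`, `beta`, `se`, `z`, `p_raw`, `p_gc`,
#'   `untestable`), `lambda` (named per-model inflation factors),
#'   `gc_method`, `n_tested` per model, and `models`.
#' @export
genome_scan <- function(gm, y, nf,
                        models = c("dominance", "recessive", "overdominance"),
                        gc_method = c("median", "regression")) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(nf, "null_fit"))
  gc_method <- match.arg(gc_method)
  models <- match.arg(models, CODING_MODELS, several.ok = TRUE)
  models <- union(models, "additive")
  if (!is.null(nf$ids) && !identical(as.character(gm$ids),
                                     as.character(nf$ids)))
    stop("individual ids (or their order) differ between the genotype ",
         "matrix and the null fit; align them explicitly first")
  n <- nf$n
  if (nrow(gm$dosages) != n)
    stop("genotype matrix has ", nrow(gm$dosages),
         " individuals but the null fit has ", n)

  D <- gm$dosages
  cm <- colMeans(D, na.rm = TRUE)
  cm[is.nan(cm)] <- 0
  if (anyNA(D)) {
    idx <- which(is.na(D), arr.ind = TRUE)
    Dimp <- D
    Dimp[idx] <- cm[idx[, 2]]
  } else Dimp <- D

  # per-marker summaries on observed calls
  counts <- t(apply(D, 2, genotype_counts))
  f_b <- cm / 2
  maf <- pmin(f_b, 1 - f_b)

  w <- nf$vc$sigma_u2 * nf$eigen$values + nf$vc$sigma_e2
  re_w <- drop(crossprod(nf$eigen$vectors, nf$residuals)) / w

  res_list <- vector("list", length(models))
  lambda <- stats::setNames(numeric(length(models)), models)
  n_tested <- stats::setNames(integer(length(models)), models)
  for (k in seq_along(models)) {
    mod <- models[k]
    Xc <- code_dosage(Dimp, mod)
    Xc <- sweep(Xc, 2, colMeans(Xc))
    A <- crossprod(nf$eigen$vectors, Xc)
    den <- colSums(A^2 / w)
    num <- drop(crossprod(A, re_w))
    floor_k <- 1e-10 * pmax(1, colSums(Xc^2))
    untestable <- den <= floor_k
    beta <- ifelse(untestable, NA_real_, num / den)
    se <- ifelse(untestable, NA_real_, 1 / sqrt(den))
    z <- beta / se
    p_raw <- 2 * stats::pnorm(-abs(z))
    gc <- estimate_lambda(z[!untestable & is.finite(z)], method = gc_method)
    p_gc <- gc_adjust(z, gc)
    lambda[mod] <- gc$lambda
    n_tested[mod] <- sum(!untestable)
    res_list[[k]] <- data.frame(
      snp_id = gm$markers$snp_id, chr = gm$markers$chr,
      pos = gm$markers$pos, model = mod,
      maf = maf, n_AA = counts[, "n_AA"], n_AB = counts[, "n_AB"],
      n_BB = counts[, "n_BB"],
      beta = beta, se = se, z = z, p_raw = p_raw, p_gc = p_gc,
      untestable = untestable,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  structure(list(
    results = do.call(rbind, res_list),
    lambda = lambda,
    gc_method = gc_method,
    n_tested = n_tested,
    models = models
  ), class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat("scan_result:", length(unique(x$results$snp_id)), "markers,",
      "models:", paste(x$models, collapse = ", "), "\n")
  cat("  lambda:", paste(sprintf("%s %.3f", names(x$lambda), x$lambda),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Write a scan-result table as TSV
#'
#' Adds a `significant` flag at the Bonferroni threshold
#' `alpha / n_tested` (per model, on genomic-control-adjusted p-values)
#' and a Manhattan-ready `neglog10_p_gc` column.
#'
#' @param scan A [genome_scan()] result.
#' @param path Output path.
#' @param alpha Family-wise error rate (default 0.01).
#' @return Invisibly, the augmented data frame.
#' @export
write_scan_tsv <- function(scan, path, alpha = 0.01) {
  stopifnot(inherits(scan, "scan_result"))
  df <- scan$results
  thr <- vapply(df$model, function(m)
    bonferroni_threshold(alpha, scan$n_tested[[m]]), 0)
  df$significant <- !is.na(df$p_gc) & df$p_gc < thr
  df$neglog10_p_gc <- -log10(df$p_gc)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
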