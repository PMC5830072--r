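# Marker QC filters and the four genotype codings.

#' Genotype coding models
#'
#' The four single-column codings of a biallelic genotype (dosage = number
#' of copies of the B allele): additive maps (0,1,2) -> (0,1,2); dominance
#' (one copy of B acts like two) -> (0,1,1); recessive (only the BB
#' homozygote deviates) -> (0,0,1); overdominance (the heterozygote
#' deviates from both homozygotes) -> (0,1,0).
#'
#' @format Character vector of the four model names.
#' @export
CODING_MODELS <- c("additive", "dominance", "recessive", "overdominance")

#' Encode genotype dosages under a coding model
#'
#' Maps B-allele dosages through one of the four coding models. Missing
#' dosages are first mean-imputed on the dosage scale (per-vector mean of
#' observed calls) and then mapped through the coding treated as a
#' piecewise-linear function of dosage, which preserves column means and
#' keeps the dominance - recessive = overdominance identity exact for
#' fractional imputed values.
#'
#' @param dosages Numeric vector with entries 0, 1, 2 or `NA`.
#' @param model One of `"additive"`, `"dominance"`, `"recessive"`,
#'   `"overdominance"`.
#' @return Numeric coded vector of the same length.
#' @export
encode_genotypes <- function(dosages, model) {
  model <- match.arg(model, CODING_MODELS)
  ok <- dosages %in% c(0, 1, 2) | is.na(dosages)
  if (!all(ok))
    stop("dosages must be 0, 1, 2 or NA")
  d <- as.double(dosages)
  if (anyNA(d)) {
    mu <- mean(d, na.rm = TRUE)
    if (is.nan(mu)) mu <- 0   # all-missing column: impute 0
    d[is.na(d)] <- mu
  }
  code_dosage(d, model)
}

# piecewise-linear coding map, exact at integer dosages, defined on [0, 2]
code_dosage <- function(d, model) {
  switch(model,
    additive      = d,
    dominance     = pmin(d, 1),
    recessive     = pmax(d - 1, 0),
    overdominance = 1 - abs(d - 1)
  )
}

#' Minor allele frequency from genotype counts
#'
#' Computes the B-allele frequency `(2 n_BB + n_AB) / (2 n)` from genotype
#' class counts and folds it to the minor allele frequency
#' `min(f, 1 - f)`.
#'
#' @param n_AA,n_AB,n_BB Non-negative genotype class counts.
#' @return Minor allele frequency in `[0, 0.5]`.
#' @export
compute_maf <- function(n_AA, n_AB, n_BB) {
  if (any(c(n_AA, n_AB, n_BB) < 0))
    stop("genotype counts must be non-negative")
  total <- n_AA + n_AB + n_BB
  if (total == 0) stop("total genotype count is zero; MAF undefined")
  f_b <- (2 * n_BB + n_AB) / (2 * total)
  min(f_b, 1 - f_b)
}

#' Marker quality control
#'
#' Applies the panel-editing rules in order: (1) drop markers on sex
#' chromosomes (labels X, Y, XY, MT, or "30", the bovine X synonym);
#' (2) drop monomorphic markers (a single observed allele); (3) drop
#' markers with minor allele frequency below `maf_min`. Frequencies are
#' computed from observed (non-missing) calls so imputation can never
#' rescue a monomorphic marker. Markers with MAF exactly equal to
#' `maf_min` are retained (markers with MAF *less than* the threshold are
#' removed).
#'
#' @param gm A [genotype_matrix()].
#' @param maf_min Minimum minor allele frequency retained (default 0.01).
#' @param drop_sex_chromosomes Apply the sex-chromosome rule (default
#'   `TRUE`).
#' @return List with components `gm` (the filtered [genotype_matrix()])
#'   and `report` (data frame: `rule`, `n_removed`, `n_retained`).
#' @export
qc_filter <- function(gm, maf_min = 0.01, drop_sex_chromosomes = TRUE) {
  stopifnot(inherits(gm, "genotype_matrix"))
  keep <- rep(TRUE, nrow(gm$markers))
  report <- data.frame(rule = character(), n_removed = integer(),
                       n_retained = integer(), stringsAsFactors = FALSE)
  note <- function(rule, removed) {
    report <<- rbind(report, data.frame(
      rule = rule, n_removed = removed, n_retained = sum(keep),
      stringsAsFactors = FALSE))
  }

  if (drop_sex_chromosomes) {
    sexy <- keep & gm$markers$chr %in% SEX_CHROM_LABELS
    keep[sexy] <- FALSE
    note("sex_chromosome", sum(sexy))
  } else {
    note("sex_chromosome", 0L)
  }

  # observed B-allele frequency per marker
  f_b <- colMeans(gm$dosages, na.rm = TRUE) / 2
  f_b[is.nan(f_b)] <- 0  # all-missing marker: treat as monomorphic

  mono <- keep & (f_b == 0 | f_b == 1)
  keep[mono] <- FALSE
  note("monomorphic", sum(mono))

  maf <- pmin(f_b, 1 - f_b)
  low <- keep & (maf < maf_min)
  keep[low] <- FALSE
  note("low_maf", sum(low))

  if (!any(keep))
    stop("QC removed every marker; the panel is empty")

  out <- genotype_matrix(gm$dosages[, keep, drop = FALSE], gm$ids,
                         gm$markers[keep, , drop = FALSE])
  list(gm = out, report = report)
}

#' Genotype class counts for a marker
#'
#' Tabulates observed dosages into the AA / AB / BB classes (dosage 0, 1,
#' 2 with respect to the B allele). Missing calls are excluded.
#'
#' @param dosages Numeric dosage vector.
#' @return Named integer vector `c(n_AA, n_AB, n_BB)`.
#' @export
genotype_counts <- function(dosages) {
  c(n_AA = sum(dosages == 0, na.rm = TRUE),
    n_AB = sum(dosages == 1, na.rm = TRUE),
    n_BB = sum(dosages == 2, na.rm = TRUE))
}
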