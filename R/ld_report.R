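# Post-scan reporting: pairwise LD, top-marker tables, genotype-class
# phenotype summaries, Manhattan data.

#' Pairwise composite LD (r-squared) among selected markers
#'
#' Squared Pearson correlation of unphased genotype dosages over the
#' individuals complete for each pair of markers (composite LD — the
#' standard measure when phase is unavailable). A marker with zero
#' dosage variance is untestable and its row and column are `NA`.
#'
#' @param gm A [genotype_matrix()].
#' @param marker_ids Character vector of at least two marker ids.
#' @return Object of class `ld_matrix`: `r2` (symmetric matrix with unit
#'   diagonal for testable markers) and `marker_ids`.
#' @export
pairwise_r2 <- function(gm, marker_ids) {
  stopifnot(inherits(gm, "genotype_matrix"))
  miss <- setdiff(marker_ids, gm$markers$snp_id)
  if (length(miss))
    stop("marker(s) not in panel: ", paste(miss, collapse = ", "))
  if (length(marker_ids) < 2) stop("need at least two markers for LD")
  D <- gm$dosages[, marker_ids, drop = FALSE]
  vr <- apply(D, 2, stats::var, na.rm = TRUE)
  r <- suppressWarnings(stats::cor(D, use = "pairwise.complete.obs"))
  r2 <- r^2
  bad <- !is.finite(vr) | vr == 0
  r2[bad, ] <- NA_real_
  r2[, bad] <- NA_real_
  diag(r2)[!bad] <- 1
  r2 <- pmin(pmax(r2, 0), 1)
  structure(list(r2 = r2, marker_ids = marker_ids), class = "ld_matrix")
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat("ld_matrix:", length(x$marker_ids), "markers (composite r2)\n")
  print(round(x$r2, 3))
  invisible(x)
}

#' Table of top non-additive associations
#'
#' Builds the publication-style table of markers whose
#' genomic-control-adjusted p-value under a non-additive coding passes
#' the significance threshold: marker, map position, MAF, genotype
#' counts, effect and standard error, the non-additive p-value, and the
#' additive p-value of the same marker from the co-computed additive
#' scan. Rows are sorted by model, then chromosome, then position.
#'
#' @param scan A [genome_scan()] result that includes the additive model.
#' @param threshold Per-test significance threshold (e.g. from
#'   [bonferroni_threshold()]).
#' @return Data frame (possibly empty, header always defined) with
#'   columns `snp_id`, `chr`, `pos`, `model`, `maf`, `n_AA`, `n_AB`,
#'   `n_BB`, `beta`, `se`, `p_nonadd`, `p_add`.
#' @export
results_table <- function(scan, threshold) {
  stopifnot(inherits(scan, "scan_result"))
  df <- scan$results
  add <- df[df$model == "additive", c("snp_id", "p_gc")]
  names(add)[2] <- "p_add"
  na_models <- setdiff(scan$models, "additive")
  sig <- df[df$model %in% na_models & !df$untestable &
              !is.na(df$p_gc) & df$p_gc < threshold, , drop = FALSE]
  out <- data.frame(
    snp_id = sig$snp_id, chr = sig$chr, pos = sig$pos, model = sig$model,
    maf = sig$maf, n_AA = sig$n_AA, n_AB = sig$n_AB, n_BB = sig$n_BB,
    beta = sig$beta, se = sig$se, p_nonadd = sig$p_gc,
    stringsAsFactors = FALSE
  )
  out$p_add <- add$p_add[match(out$snp_id, add$snp_id)]
  ord <- order(match(out$model, CODING_MODELS), out$chr, out$pos)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Phenotype summaries per genotype class
#'
#' Summary statistics of the raw phenotype stratified by the AA/AB/BB
#' genotype classes of one marker (the data behind a genotype-stratified
#' box plot). Individuals with a missing call at the marker are excluded;
#' an empty class is reported with `n = 0` and `NA` statistics.
#'
#' @param gm A [genotype_matrix()].
#' @param y Numeric phenotype vector aligned with `gm`.
#' @param marker_id Marker to stratify on.
#' @return Data frame with one row per class: `class`, `n`, `mean`,
#'   `median`, `q1`, `q3`.
#' @export
genotype_phenotype_summary <- function(gm, y, marker_id) {
  stopifnot(inherits(gm, "genotype_matrix"))
  j <- match(marker_id, gm$markers$snp_id)
  if (is.na(j)) stop("marker not in panel: ", marker_id)
  d <- gm$dosages[, j]
  cls <- c(AA = 0, AB = 1, BB = 2)
  rows <- lapply(names(cls), function(cl) {
    yy <- y[!is.na(d) & d == cls[[cl]]]
    if (length(yy) == 0) {
      data.frame(class = cl, n = 0L, mean = NA_real_, median = NA_real_,
                 q1 = NA_real_, q3 = NA_real_, stringsAsFactors = FALSE)
    } else {
      q <- stats::quantile(yy, c(0.25, 0.5, 0.75), names = FALSE)
      data.frame(class = cl, n = length(yy), mean = mean(yy),
                 median = q[2], q1 = q[1], q3 = q[3],
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Manhattan-plot data
#'
#' Extracts the plotting data for Manhattan plots: position and
#' `-log10(p_gc)` per marker per model.
#'
#' @param scan A [genome_scan()] result.
#' @return Data frame: `snp_id`, `chr`, `pos`, `model`, `neglog10_p_gc`.
#' @export
manhattan_data <- function(scan) {
  stopifnot(inherits(scan, "scan_result"))
  df <- scan$results
  data.frame(snp_id = df$snp_id, chr = df$chr, pos = df$pos,
             model = df$model, neglog10_p_gc = -log10(df$p_gc),
             stringsAsFactors = FALSE)
}
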