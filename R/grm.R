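# Genomic relationship matrix (VanRaden method 1).

#' Compute the genomic relationship matrix
#'
#' VanRaden's first method: with dosage matrix `X` (columns mean-imputed)
#' and sample B-allele frequencies `p_j`, the centred matrix
#' `W = X - 2p` gives `G = W W' / (2 sum_j p_j (1 - p_j))`. A small ridge
#' is added to the diagonal so that `G` (and hence the null covariance
#' built from it) is safely positive definite.
#'
#' @param gm A [genotype_matrix()]; run [qc_filter()] first so at least
#'   two polymorphic markers remain.
#' @param ridge Positive stabiliser added to the diagonal (default 1e-6).
#' @return Object of class `grm`: list with `g` (symmetric n x n matrix),
#'   `ids`, `ridge`, and `n_markers` used.
#' @export
compute_grm <- function(gm, ridge = 1e-6) {
  stopifnot(inherits(gm, "genotype_matrix"))
  X <- gm$dosages
  cm <- colMeans(X, na.rm = TRUE)
  cm[is.nan(cm)] <- 0
  if (anyNA(X)) {
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- cm[idx[, 2]]
  }
  p <- cm / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0)
    stop("all markers are monomorphic; run qc_filter() before compute_grm()")
  W <- sweep(X, 2, 2 * p)
  G <- tcrossprod(W) / denom
  G <- (G + t(G)) / 2           # enforce exact symmetry
  diag(G) <- diag(G) + ridge
  dimnames(G) <- list(gm$ids, gm$ids)
  structure(list(g = G, ids = gm$ids, ridge = ridge,
                 n_markers = ncol(X)),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("grm:", length(x$ids), "individuals,", x$n_markers,
      "markers, ridge", x$ridge, "\n")
  cat("  mean diagonal:", round(mean(diag(x$g)), 4), "\n")
  invisible(x)
}

#' Export a GRM as a square CSV
#'
#' @param grm A [compute_grm()] result.
#' @param path Output path; square matrix with an id header column.
#' @return Invisibly, `path`.
#' @export
write_grm_csv <- function(grm, path) {
  stopifnot(inherits(grm, "grm"))
  df <- data.frame(id = grm$ids, grm$g, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a GRM from a square CSV
#'
#' @param path Path written by [write_grm_csv()].
#' @param ridge Ridge recorded in the returned object (informational; the
#'   stored matrix already includes it).
#' @return A `grm` object.
#' @export
read_grm_csv <- function(path, ridge = NA_real_) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df$id)
  g <- as.matrix(df[, -1, drop = FALSE])
  dimnames(g) <- list(ids, ids)
  structure(list(g = g, ids = ids, ridge = ridge, n_markers = NA_integer_),
            class = "grm")
}
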