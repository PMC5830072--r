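# Synthetic genotype/phenotype generator: paternal half-sib families,
# polygenic background drawn from the genomic relationship matrix, and
# planted QTLs acting under any of the four codings.

#' QTL specification
#'
#' One planted quantitative trait locus: the marker it sits on, the mode
#' of gene action, and the phenotype-unit effect of one coded unit.
#'
#' @param snp_index 1-based marker index.
#' @param model One of `"additive"`, `"dominance"`, `"recessive"`,
#'   `"overdominance"`.
#' @param effect Finite effect in phenotype units per coded genotype unit.
#' @return A list of class `qtl_spec`.
#' @export
qtl_spec <- function(snp_index, model, effect) {
  model <- match.arg(model, CODING_MODELS)
  if (!is.finite(effect)) stop("QTL effect must be finite")
  if (snp_index < 1) stop("snp_index must be >= 1")
  structure(list(snp_index = as.integer(snp_index), model = model,
                 effect = effect), class = "qtl_spec")
}

#' Simulation configuration
#'
#' Parameters of the synthetic-data generator. The population is a set of
#' paternal half-sib families: each of `n_sires` sires passes one gamete
#' to each of its `offspring_per_sire` genotyped offspring, and the dam
#' allele is drawn from the population frequency (dams unobserved).
#' Setting `offspring_per_sire = 1` yields an effectively unrelated
#' sample. Per-marker B-allele frequencies are drawn uniformly on
#' `[maf_low, maf_high]`.
#'
#' @param n_sires Number of sires (families).
#' @param offspring_per_sire Genotyped offspring per sire.
#' @param n_snps Number of markers.
#' @param maf_low,maf_high Allele-frequency bounds, `0 < maf_low <=
#'   maf_high <= 0.5`.
#' @param qtl_specs List of [qtl_spec()] objects (may be empty).
#' @param sigma_u2 Polygenic variance (phenotype units squared, >= 0).
#' @param sigma_e2 Residual variance (phenotype units squared, > 0).
#' @param mu Phenotype intercept (default 0: the trait is expressed as a
#'   deviation from the population mean).
#' @param seed Integer RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_sires, offspring_per_sire, n_snps,
                       maf_low = 0.05, maf_high = 0.5,
                       qtl_specs = list(), sigma_u2 = 0.3,
                       sigma_e2 = 0.7, mu = 0, seed = 1L) {
  if (!(maf_low > 0 && maf_low <= maf_high && maf_high <= 0.5))
    stop("require 0 < maf_low <= maf_high <= 0.5")
  if (sigma_u2 < 0) stop("sigma_u2 must be >= 0")
  if (sigma_e2 <= 0) stop("sigma_e2 must be > 0")
  if (n_sires < 1 || offspring_per_sire < 1 || n_snps < 1)
    stop("n_sires, offspring_per_sire and n_snps must be >= 1")
  for (q in qtl_specs) {
    if (!inherits(q, "qtl_spec")) stop("qtl_specs must contain qtl_spec objects")
    if (q$snp_index > n_snps)
      stop("QTL snp_index ", q$snp_index, " exceeds n_snps = ", n_snps)
  }
  structure(list(
    n_sires = as.integer(n_sires),
    offspring_per_sire = as.integer(offspring_per_sire),
    n_snps = as.integer(n_snps),
    maf_low = maf_low, maf_high = maf_high,
    qtl_specs = qtl_specs, sigma_u2 = sigma_u2, sigma_e2 = sigma_e2,
    mu = mu, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate genotypes for paternal half-sib families
#'
#' Draws per-marker B-allele frequencies uniformly on
#' `[maf_low, maf_high]`, simulates each sire's two gametes from those
#' frequencies, and builds each offspring's genotype as one paternal
#' gamete (picked at random per marker — markers segregate
#' independently; no linkage map is simulated) plus one population dam
#' allele. Paternal half sibs therefore share alleles identically by
#' descent with expected genomic relationship 0.25. Markers are assigned
#' round-robin to autosomes 1..29 with increasing positions. Output is a
#' pure function of the configuration (including its seed).
#'
#' @param config A [sim_config()].
#' @return A [genotype_matrix()] of the offspring; the drawn allele
#'   frequencies are attached as attribute `"allele_freq"` and the sire
#'   of each individual as attribute `"sire"`.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m <- config$n_snps
  ns <- config$n_sires
  ops <- config$offspring_per_sire
  n <- ns * ops
  p <- stats::runif(m, config$maf_low, config$maf_high)

  # sire gametes: two haplotypes per sire
  h1 <- matrix(stats::rbinom(ns * m, 1, rep(p, each = ns)), ns, m)
  h2 <- matrix(stats::rbinom(ns * m, 1, rep(p, each = ns)), ns, m)

  sire_of <- rep(seq_len(ns), each = ops)
  pick <- matrix(stats::runif(n * m) < 0.5, n, m)
  pat <- ifelse(pick, h1[sire_of, , drop = FALSE], h2[sire_of, , drop = FALSE])
  dam <- matrix(stats::rbinom(n * m, 1, rep(p, each = n)), n, m)
  dos <- pat + dam

  ids <- sprintf("S%04d_O%03d", sire_of, sequence(rep(ops, ns)))
  chr <- as.character(((seq_len(m) - 1L) %% 29L) + 1L)
  pos <- (((seq_len(m) - 1L) %/% 29L) + 1L) * 10000L
  markers <- data.frame(
    snp_id = sprintf("snp%05d", seq_len(m)), chr = chr, pos = pos,
    allele_a = "A", allele_b = "B", stringsAsFactors = FALSE
  )
  gm <- genotype_matrix(dos, ids, markers)
  attr(gm, "allele_freq") <- p
  attr(gm, "sire") <- sire_of
  gm
}

#' Genetic values from planted QTLs
#'
#' Sums, over the planted QTLs, `effect * code(dosage, model)` per
#' individual, using the same coding maps as the scan.
#'
#' @param gm A [genotype_matrix()].
#' @param specs List of [qtl_spec()] objects.
#' @return Numeric genetic-value vector (all zero for an empty list).
#' @export
plant_qtls <- function(gm, specs) {
  stopifnot(inherits(gm, "genotype_matrix"))
  g <- numeric(length(gm$ids))
  for (q in specs) {
    if (!inherits(q, "qtl_spec")) stop("specs must contain qtl_spec objects")
    if (q$snp_index > ncol(gm$dosages))
      stop("QTL snp_index ", q$snp_index, " out of range (",
           ncol(gm$dosages), " markers)")
    g <- g + q$effect * encode_genotypes(gm$dosages[, q$snp_index], q$model)
  }
  g
}

#' Simulate phenotypes over a genotype matrix
#'
#' Builds `y = mu + sum_q effect_q code_q + u + e`, with the polygenic
#' term `u ~ N(0, G sigma_u2)` drawn through the eigendecomposition of
#' the genomic relationship matrix computed from `gm` itself, and
#' `e ~ N(0, I sigma_e2)` i.i.d. Returns the phenotype vector with a
#' ground-truth table recording each planted QTL and the realised
#' variance partition.
#'
#' @param gm A [genotype_matrix()].
#' @param specs List of [qtl_spec()] objects.
#' @param sigma_u2 Polygenic variance (>= 0).
#' @param sigma_e2 Residual variance (> 0).
#' @param mu Intercept (default 0).
#' @param seed Integer RNG seed.
#' @return List with `y` (named numeric vector), `truth` (data frame:
#'   `snp_id`, `snp_index`, `model`, `effect`, realised genotype-class
#'   frequencies `freq_AA`, `freq_AB`, `freq_BB`), and `components`
#'   (realised variances of the QTL, polygenic and residual terms plus
#'   the target `h2`).
#' @export
simulate_phenotypes <- function(gm, specs, sigma_u2, sigma_e2, mu = 0,
                                seed = 1L) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (sigma_u2 < 0) stop("sigma_u2 must be >= 0")
  if (sigma_e2 <= 0) stop("sigma_e2 must be > 0")
  n <- length(gm$ids)
  set.seed(seed)
  gq <- plant_qtls(gm, specs)
  if (sigma_u2 > 0) {
    G <- compute_grm(gm)
    eg <- eigen(G$g, symmetric = TRUE)
    ev <- pmax(eg$values, 0)
    if (min(eg$values) < -1e-6)
      stop("GRM is not positive semi-definite (min eigenvalue ",
           format(min(eg$values)), "); check the genotype input")
    u <- drop(eg$vectors %*% (sqrt(ev) * stats::rnorm(n))) * sqrt(sigma_u2)
  } else {
    u <- numeric(n)
  }
  e <- stats::rnorm(n, 0, sqrt(sigma_e2))
  y <- mu + gq + u + e
  names(y) <- gm$ids

  truth <- do.call(rbind, lapply(specs, function(q) {
    d <- gm$dosages[, q$snp_index]
    cnt <- genotype_counts(d)
    tot <- sum(cnt)
    data.frame(snp_id = gm$markers$snp_id[q$snp_index],
               snp_index = q$snp_index, model = q$model, effect = q$effect,
               freq_AA = cnt[["n_AA"]] / tot, freq_AB = cnt[["n_AB"]] / tot,
               freq_BB = cnt[["n_BB"]] / tot, stringsAsFactors = FALSE)
  }))
  if (is.null(truth))
    truth <- data.frame(snp_id = character(), snp_index = integer(),
                        model = character(), effect = numeric(),
                        freq_AA = numeric(), freq_AB = numeric(),
                        freq_BB = numeric(), stringsAsFactors = FALSE)
  components <- list(
    var_qtl = if (length(specs)) stats::var(gq) else 0,
    var_u = if (sigma_u2 > 0) stats::var(u) else 0,
    var_e = stats::var(e),
    sigma_u2 = sigma_u2, sigma_e2 = sigma_e2,
    h2_target = sigma_u2 / (sigma_u2 + sigma_e2)
  )
  list(y = y, truth = truth, components = components)
}

#' Simulate a complete dataset from a configuration
#'
#' Convenience wrapper: genotypes from `config`, phenotypes with the
#' config's variances and QTLs. The phenotype seed is derived from the
#' config seed so the whole dataset is a pure function of the
#' configuration.
#'
#' @param config A [sim_config()].
#' @return List: `gm`, `y`, `truth`, `components`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  gm <- simulate_genotypes(config)
  ph <- simulate_phenotypes(gm, config$qtl_specs, config$sigma_u2,
                            config$sigma_e2, mu = config$mu,
                            seed = config$seed + 1L)
  list(gm = gm, y = ph$y, truth = ph$truth, components = ph$components)
}
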