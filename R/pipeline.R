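# End-to-end pipeline drivers: simulate / scan / report. These back the
# command-line interface (inst/cli/nonaddscan) and are directly callable.

read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML path")
  config
}

require_keys <- function(config, keys) {
  miss <- setdiff(keys, names(config))
  if (length(miss))
    stop("config lacks required key(s): ", paste(miss, collapse = ", "))
}

write_manifest <- function(path, entries) {
  entries$package_version <- as.character(utils::packageVersion("nonaddscan"))
  entries$r_version <- paste(R.version$major, R.version$minor, sep = ".")
  jsonlite::write_json(entries, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Simulate a dataset and write it to disk
#'
#' Wraps the simulate module: generates genotypes and phenotypes from a
#' configuration and writes PLINK text `.ped`/`.map`, a phenotype TSV
#' (`id`, `phenotype`), a ground-truth TSV (one row per planted QTL),
#' and a machine-readable run manifest.
#'
#' Config keys (YAML file or list): `n_sires`, `offspring_per_sire`,
#' `n_snps`; optional `maf_low`, `maf_high`, `sigma_u2`, `sigma_e2`,
#' `mu`, `seed`, and `qtls` (list of `snp_index` / `model` / `effect`
#' entries).
#'
#' @param config Path to a YAML file or a named list.
#' @param out_prefix Output path prefix.
#' @param seed Optional seed override.
#' @return Invisibly, a named vector of the written file paths.
#' @export
run_simulate <- function(config, out_prefix, seed = NULL) {
  cfg <- read_run_config(config)
  require_keys(cfg, c("n_sires", "offspring_per_sire", "n_snps"))
  if (!is.null(seed)) cfg$seed <- seed
  qtls <- lapply(cfg$qtls, function(q)
    qtl_spec(q$snp_index, q$model, q$effect))
  sc <- sim_config(
    n_sires = cfg$n_sires, offspring_per_sire = cfg$offspring_per_sire,
    n_snps = cfg$n_snps,
    maf_low = cfg$maf_low %||% 0.05, maf_high = cfg$maf_high %||% 0.5,
    qtl_specs = qtls,
    sigma_u2 = cfg$sigma_u2 %||% 0.3, sigma_e2 = cfg$sigma_e2 %||% 0.7,
    mu = cfg$mu %||% 0, seed = cfg$seed %||% 1L
  )
  ds <- simulate_dataset(sc)
  files <- write_plink_text(ds$gm, out_prefix)
  pheno_path <- paste0(out_prefix, "_phenotypes.tsv")
  write_phenotypes(ds$y, pheno_path)
  truth_path <- paste0(out_prefix, "_truth.tsv")
  utils::write.table(ds$truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest_path <- paste0(out_prefix, "_manifest.json")
  write_manifest(manifest_path, list(
    command = "simulate", seed = sc$seed,
    n_individuals = length(ds$gm$ids), n_snps = sc$n_snps,
    n_qtls = length(qtls),
    config = cfg[setdiff(names(cfg), "qtls")]
  ))
  invisible(c(files, phenotypes = pheno_path, truth = truth_path,
              manifest = manifest_path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_genotypes <- function(cfg) {
  if (!is.null(cfg$ped) && !is.null(cfg$map)) {
    read_plink_text(cfg$ped, cfg$map)
  } else if (!is.null(cfg$dosage_csv)) {
    read_dosage_csv(cfg$dosage_csv)
  } else {
    stop("config must provide either 'ped' + 'map' or 'dosage_csv'")
  }
}

#' Run the full two-step genome scan
#'
#' Binds the pipeline end to end: read genotypes and phenotypes, align
#' individuals, QC-filter the panel, build the genomic relationship
#' matrix, fit the null animal model by REML, scan all requested coding
#' models (the additive model is always co-computed), apply genomic
#' control and the Bonferroni threshold, and write the scan table, the
#' null-fit summary, the QC report, a per-model correction summary, and
#' a run manifest.
#'
#' Config keys: genotype input (`ped` + `map`, or `dosage_csv`),
#' `phenotypes`; optional `covariates` (CSV/TSV: `id` + numeric
#' columns), `maf_min` (default 0.01), `models` (default the three
#' non-additive codings), `gc_method` (default `"median"`), `alpha`
#' (default 0.01), `grm_ridge` (default 1e-6).
#'
#' @param config Path to a YAML file or a named list.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory objects: `gm`, `y`,
#'   `qc_report`, `null_fit`, `scan`, `threshold`.
#' @export
run_scan <- function(config, out_dir) {
  cfg <- read_run_config(config)
  require_keys(cfg, "phenotypes")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  gm <- load_genotypes(cfg)
  ph <- read_phenotypes(cfg$phenotypes)
  missing_ids <- setdiff(gm$ids, ph$id)
  extra_ids <- setdiff(ph$id, gm$ids)
  if (length(missing_ids))
    stop("genotyped individuals without phenotype: ",
         paste(utils::head(missing_ids, 5), collapse = ", "),
         if (length(missing_ids) > 5) " ..." else "")
  y <- ph$phenotype[match(gm$ids, ph$id)]
  if (length(extra_ids))
    message(length(extra_ids), " phenotyped individuals without genotypes ",
            "were dropped")

  X <- NULL
  if (!is.null(cfg$covariates)) {
    cov <- read_phenotype_like(cfg$covariates)
    miss <- setdiff(gm$ids, cov$id)
    if (length(miss))
      stop("covariate table lacks individual(s): ",
           paste(utils::head(miss, 5), collapse = ", "))
    cm <- as.matrix(cov[match(gm$ids, cov$id),
                        setdiff(names(cov), "id"), drop = FALSE])
    storage.mode(cm) <- "double"
    X <- cbind(intercept = 1, cm)
  }

  qc <- qc_filter(gm, maf_min = cfg$maf_min %||% 0.01)
  utils::write.table(qc$report, file.path(out_dir, "qc_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  G <- compute_grm(qc$gm, ridge = cfg$grm_ridge %||% 1e-6)
  nf <- fit_null(y, X = X, G = G)
  jsonlite::write_json(null_fit_summary(nf, ncol(qc$gm$dosages)),
                       file.path(out_dir, "null_fit.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  models <- cfg$models %||% c("dominance", "recessive", "overdominance")
  scan <- genome_scan(qc$gm, y, nf, models = models,
                      gc_method = cfg$gc_method %||% "median")
  alpha <- cfg$alpha %||% 0.01
  write_scan_tsv(scan, file.path(out_dir, "scan.tsv"), alpha = alpha)

  correction <- lapply(scan$models, function(m) {
    thr <- bonferroni_threshold(alpha, scan$n_tested[[m]])
    sub <- scan$results[scan$results$model == m, ]
    list(model = m, lambda = scan$lambda[[m]], method = scan$gc_method,
         m = scan$n_tested[[m]], alpha = alpha, threshold = thr,
         n_significant = sum(!is.na(sub$p_gc) & sub$p_gc < thr))
  })
  jsonlite::write_json(correction, file.path(out_dir, "correction.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  thr_table <- bonferroni_threshold(alpha,
                                    max(scan$n_tested[setdiff(scan$models,
                                                              "additive")]))
  write_manifest(file.path(out_dir, "manifest.json"), list(
    command = "scan", n_individuals = length(gm$ids),
    n_markers_input = nrow(gm$markers),
    n_markers_tested = ncol(qc$gm$dosages),
    models = scan$models, gc_method = scan$gc_method,
    lambda = as.list(scan$lambda), alpha = alpha,
    h2 = nf$vc$h2, sigma_u2 = nf$vc$sigma_u2, sigma_e2 = nf$vc$sigma_e2
  ))
  invisible(list(gm = qc$gm, y = y, qc_report = qc$report, null_fit = nf,
                 scan = scan, threshold = thr_table))
}

read_phenotype_like <- function(path) {
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE)
}

#' Regenerate reports from a saved scan
#'
#' Reads the `scan.tsv` written by [run_scan()] together with the
#' genotype and phenotype inputs, and regenerates the top-marker table,
#' the pairwise-LD matrix over the significant markers (by default), the
#' genotype-class phenotype summaries for the significant markers, and
#' the Manhattan data file.
#'
#' @param config Path to a YAML file or list with the same genotype /
#'   phenotype keys as [run_scan()], plus optional `alpha` and
#'   `ld_markers` (explicit marker ids for the LD matrix).
#' @param scan_dir Directory holding the [run_scan()] outputs.
#' @param out_dir Output directory (default `scan_dir`).
#' @return Invisibly, a list: `table`, `ld`, `summaries`.
#' @export
run_report <- function(config, scan_dir, out_dir = scan_dir) {
  cfg <- read_run_config(config)
  scan_path <- file.path(scan_dir, "scan.tsv")
  if (!file.exists(scan_path))
    stop("no scan.tsv under ", scan_dir, "; run the scan first")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  df <- utils::read.table(scan_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(chr = "character"))
  models <- unique(df$model)
  scan <- structure(list(
    results = df, models = models,
    lambda = stats::setNames(rep(NA_real_, length(models)), models),
    gc_method = "saved",
    n_tested = stats::setNames(
      vapply(models, function(m) sum(df$model == m & !df$untestable), 0L),
      models)
  ), class = "scan_result")

  gm <- load_genotypes(cfg)
  ph <- read_phenotypes(cfg$phenotypes)
  y <- ph$phenotype[match(gm$ids, ph$id)]

  alpha <- cfg$alpha %||% 0.01
  na_models <- setdiff(models, "additive")
  thr <- bonferroni_threshold(alpha, max(scan$n_tested[na_models]))
  tab <- results_table(scan, thr)
  utils::write.table(tab, file.path(out_dir, "top_markers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ld_ids <- cfg$ld_markers %||% unique(tab$snp_id)
  ld <- NULL
  if (length(ld_ids) >= 2) {
    ld <- pairwise_r2(gm, ld_ids)
    ld_df <- data.frame(id = ld$marker_ids, ld$r2, check.names = FALSE)
    utils::write.csv(ld_df, file.path(out_dir, "ld_r2.csv"),
                     row.names = FALSE)
  }

  summaries <- lapply(unique(tab$snp_id), function(id)
    cbind(snp_id = id, genotype_phenotype_summary(gm, y, id)))
  if (length(summaries)) {
    utils::write.table(do.call(rbind, summaries),
                       file.path(out_dir, "class_summaries.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    utils::write.table(
      data.frame(snp_id = character(), class = character(), n = integer(),
                 mean = numeric(), median = numeric(), q1 = numeric(),
                 q3 = numeric()),
      file.path(out_dir, "class_summaries.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  utils::write.table(manhattan_data(scan),
                     file.path(out_dir, "manhattan.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(table = tab, ld = ld, summaries = summaries))
}
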