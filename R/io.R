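# Genotype container and text-format readers/writers.

#' Construct a genotype matrix
#'
#' Container for a diploid biallelic SNP panel: an individuals-by-markers
#' dosage matrix (counts of the B allele, `NA` for missing calls) together
#' with individual identifiers and per-marker metadata.
#'
#' @param dosages Numeric matrix, individuals in rows, markers in columns.
#'   Entries must be 0, 1, 2 or `NA`.
#' @param ids Character vector of individual identifiers, one per row.
#' @param markers Data frame with one row per marker and columns `snp_id`,
#'   `chr`, `pos`, `allele_a`, `allele_b`. Dosage counts copies of
#'   `allele_b`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, ids, markers) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (nrow(dosages) != length(ids))
    stop("number of rows of 'dosages' (", nrow(dosages),
         ") does not match number of ids (", length(ids), ")")
  if (ncol(dosages) != nrow(markers))
    stop("number of columns of 'dosages' (", ncol(dosages),
         ") does not match number of markers (", nrow(markers), ")")
  need <- c("snp_id", "chr", "pos", "allele_a", "allele_b")
  miss <- setdiff(need, names(markers))
  if (length(miss))
    stop("marker table lacks column(s): ", paste(miss, collapse = ", "))
  ok <- dosages %in% c(0, 1, 2) | is.na(dosages)
  if (!all(ok))
    stop("dosages must be 0, 1, 2 or NA; found ",
         paste(unique(dosages[!ok])[1:min(3, sum(!ok))], collapse = ", "))
  if (anyDuplicated(ids))
    stop("individual ids must be unique")
  if (any(markers$pos < 1, na.rm = TRUE))
    stop("marker positions must be >= 1")
  dimnames(dosages) <- list(as.character(ids), as.character(markers$snp_id))
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  rownames(markers) <- NULL
  structure(
    list(dosages = dosages, ids = as.character(ids), markers = markers),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$ids), "individuals x",
      nrow(x$markers), "markers\n")
  nm <- sum(is.na(x$dosages))
  if (nm > 0) cat("  missing calls:", nm, "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

# sex-chromosome labels recognised by the QC filter ("30" is a bovine X synonym)
SEX_CHROM_LABELS <- c("X", "Y", "XY", "MT", "30")

#' Read genotypes from PLINK text files
#'
#' Parses a PLINK 1.x text `.ped`/`.map` pair into a [genotype_matrix()].
#' Dosage counts copies of the B allele, defined as the second distinct
#' allele symbol encountered per marker while scanning the `.ped` file in
#' row order (a stable, file-defined orientation). The genotype `0 0` is
#' treated as missing.
#'
#' @param ped_path Path to the `.ped` file (6 leading fields, then two
#'   allele columns per marker).
#' @param map_path Path to the `.map` file (chromosome, snp id, genetic
#'   distance, position).
#' @return A [genotype_matrix()]. Individual ids are taken from the
#'   within-family id (second `.ped` column).
#' @export
read_plink_text <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop("ped file not found: ", ped_path)
  if (!file.exists(map_path)) stop("map file not found: ", map_path)

  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  if (length(map_lines)) {
    mf <- strsplit(trimws(map_lines), "[ \t]+")
    bad <- which(lengths(mf) < 4L)
    if (length(bad))
      stop("map line ", bad[1], " has fewer than 4 fields")
    map <- data.frame(
      chr    = vapply(mf, `[`, "", 1L),
      snp_id = vapply(mf, `[`, "", 2L),
      pos    = as.numeric(vapply(mf, `[`, "", 4L)),
      stringsAsFactors = FALSE
    )
  } else {
    map <- data.frame(chr = character(), snp_id = character(),
                      pos = numeric(), stringsAsFactors = FALSE)
  }
  m <- nrow(map)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  n <- length(ped_lines)
  ids <- character(n)
  # allele symbols per marker, in order of first appearance ("0" = missing)
  a1 <- rep(NA_character_, m)
  a2 <- rep(NA_character_, m)
  al_first  <- matrix(NA_character_, n, m)
  al_second <- matrix(NA_character_, n, m)

  for (i in seq_len(n)) {
    f <- strsplit(trimws(ped_lines[i]), "[ \t]+")[[1]]
    if (length(f) != 6L + 2L * m)
      stop("ped line ", i, " has ", length(f), " fields; expected ",
           6L + 2L * m, " for ", m, " markers")
    ids[i] <- f[2L]
    if (m > 0) {
      g <- f[-(1:6)]
      al_first[i, ]  <- g[seq(1L, 2L * m, by = 2L)]
      al_second[i, ] <- g[seq(2L, 2L * m, by = 2L)]
    }
  }

  dos <- matrix(NA_real_, n, m)
  for (j in seq_len(m)) {
    obs <- c(rbind(al_first[, j], al_second[, j]))  # preserves row order
    seen <- unique(obs[obs != "0"])
    if (length(seen) > 2L)
      stop("marker ", map$snp_id[j], " has more than two allele symbols: ",
           paste(seen, collapse = ", "))
    if (length(seen) >= 1L) a1[j] <- seen[1L]
    if (length(seen) >= 2L) a2[j] <- seen[2L]
    miss <- al_first[, j] == "0" | al_second[, j] == "0"
    if (is.na(a2[j])) {
      dos[, j] <- ifelse(miss, NA_real_, 0)
    } else {
      dos[, j] <- (al_first[, j] == a2[j]) + (al_second[, j] == a2[j])
      dos[miss, j] <- NA_real_
    }
  }

  markers <- data.frame(
    snp_id = map$snp_id, chr = map$chr, pos = map$pos,
    allele_a = ifelse(is.na(a1), "0", a1),
    allele_b = ifelse(is.na(a2), "0", a2),
    stringsAsFactors = FALSE
  )
  genotype_matrix(dos, ids, markers)
}

#' Write genotypes as PLINK text files
#'
#' Emits a `.ped`/`.map` pair that round-trips through
#' [read_plink_text()]. Family id is set equal to the individual id;
#' parental ids, sex and phenotype are written as `0 0 0 -9`. Missing
#' dosages are written as the `0 0` genotype.
#'
#' @param gm A [genotype_matrix()].
#' @param out_prefix Output path prefix; `<prefix>.ped` and `<prefix>.map`
#'   are created.
#' @return Invisibly, the two file paths.
#' @export
write_plink_text <- function(gm, out_prefix) {
  stopifnot(inherits(gm, "genotype_matrix"))
  ped_path <- paste0(out_prefix, ".ped")
  map_path <- paste0(out_prefix, ".map")

  mk <- gm$markers
  map_txt <- if (nrow(mk)) {
    paste(mk$chr, mk$snp_id, 0, format(mk$pos, scientific = FALSE,
                                       trim = TRUE), sep = "\t")
  } else character()
  writeLines(map_txt, map_path)

  n <- length(gm$ids)
  m <- nrow(mk)
  lines <- character(n)
  for (i in seq_len(n)) {
    lead <- c(gm$ids[i], gm$ids[i], "0", "0", "0", "-9")
    if (m > 0) {
      d <- gm$dosages[i, ]
      # heterozygotes are written "a b" so allele A is encountered first
      g1 <- ifelse(is.na(d), "0", ifelse(d == 2, mk$allele_b, mk$allele_a))
      g2 <- ifelse(is.na(d), "0", ifelse(d >= 1, mk$allele_b, mk$allele_a))
      lines[i] <- paste(c(lead, c(rbind(g1, g2))), collapse = " ")
    } else {
      lines[i] <- paste(lead, collapse = " ")
    }
  }
  writeLines(lines, ped_path)
  invisible(c(ped = ped_path, map = map_path))
}

#' Read a phenotype table
#'
#' Reads a delimited file (tab or comma, detected from the header) with
#' columns `id`, `phenotype` and optionally `n_breedings`. If an id occurs
#' more than once, the record with the largest `n_breedings` is kept (the
#' record backed by most breedings is the most reliable one); without an
#' `n_breedings` column the last record wins and a warning is issued.
#'
#' @param path Path to the phenotype file.
#' @return Data frame with columns `id` (character) and `phenotype`
#'   (numeric), plus `n_breedings` when present; one row per id, in first
#'   appearance order.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("id", "phenotype")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("phenotype file lacks column(s): ", paste(miss, collapse = ", "))
  ph <- suppressWarnings(as.numeric(df$phenotype))
  bad <- which(is.na(ph) | !is.finite(ph))
  if (length(bad))
    stop("non-numeric or non-finite phenotype at data row ", bad[1],
         " (value '", df$phenotype[bad[1]], "')")
  df$phenotype <- ph
  has_nb <- "n_breedings" %in% names(df)
  if (has_nb) {
    nb <- suppressWarnings(as.numeric(df$n_breedings))
    if (anyNA(nb))
      stop("non-numeric n_breedings at data row ", which(is.na(nb))[1])
    df$n_breedings <- nb
  }

  if (anyDuplicated(df$id)) {
    if (has_nb) {
      # keep, per id, the record with most breedings (ties: first such)
      keep <- unlist(lapply(split(seq_len(nrow(df)), df$id), function(ix) {
        ix[which.max(df$n_breedings[ix])]
      }), use.names = FALSE)
    } else {
      warning("duplicate ids without an n_breedings column; ",
              "keeping the last record per id")
      keep <- unlist(lapply(split(seq_len(nrow(df)), df$id), function(ix) {
        ix[length(ix)]
      }), use.names = FALSE)
    }
    keep <- sort(keep)
    df <- df[keep, , drop = FALSE]
  }
  # restore first-appearance order (split() sorts by id)
  rownames(df) <- NULL
  df
}

#' Write a phenotype table
#'
#' @param phenotypes Data frame with columns `id` and `phenotype`
#'   (optionally `n_breedings`), or a named numeric vector.
#' @param path Output path; tab-separated with a header.
#' @return Invisibly, `path`.
#' @export
write_phenotypes <- function(phenotypes, path) {
  if (is.numeric(phenotypes) && !is.null(names(phenotypes)))
    phenotypes <- data.frame(id = names(phenotypes),
                             phenotype = as.numeric(phenotypes),
                             stringsAsFactors = FALSE)
  utils::write.table(phenotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a dosage-matrix CSV
#'
#' Alternative genotype input: a CSV with one row per individual, a
#' leading `id` column, and one column per marker (header = snp ids)
#' holding dosages 0/1/2 (empty or NA = missing). Marker metadata absent
#' from this dialect is filled with placeholders (chromosome "0",
#' positions 1..m, alleles A/B).
#'
#' @param path Path to the CSV file.
#' @return A [genotype_matrix()].
#' @export
read_dosage_csv <- function(path) {
  if (!file.exists(path)) stop("dosage file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "id")
    stop("first column of a dosage CSV must be 'id'")
  ids <- as.character(df$id)
  dos <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(dos) <- "double"
  markers <- data.frame(
    snp_id = colnames(dos), chr = "0", pos = seq_len(ncol(dos)),
    allele_a = "A", allele_b = "B", stringsAsFactors = FALSE
  )
  genotype_matrix(dos, ids, markers)
}

#' Write a dosage-matrix CSV
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_dosage_csv <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  df <- data.frame(id = gm$ids, gm$dosages, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
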