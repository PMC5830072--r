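# Marker QC and the four genotype codings.

test_that("the four coding maps are exactly the canonical ones", {
  d <- c(0, 1, 2)
  expect_equal(encode_genotypes(d, "additive"), c(0, 1, 2))
  expect_equal(encode_genotypes(d, "dominance"), c(0, 1, 1))
  expect_equal(encode_genotypes(d, "recessive"), c(0, 0, 1))
  expect_equal(encode_genotypes(d, "overdominance"), c(0, 1, 0))
})

test_that("additive coding is the identity on complete dosage vectors", {
  set.seed(5)
  for (i in 1:10) {
    d <- sample(0:2, 30, replace = TRUE)
    expect_identical(encode_genotypes(d, "additive"), as.numeric(d))
  }
})

test_that("dominance - recessive = overdominance, with and without missing", {
  set.seed(6)
  for (i in 1:25) {
    d <- sample(0:2, 40, replace = TRUE)
    if (i > 12) d[sample(40, 5)] <- NA  # imputation preserves the identity
    expect_equal(
      encode_genotypes(d, "dominance") - encode_genotypes(d, "recessive"),
      encode_genotypes(d, "overdominance"))
  }
})

test_that("missing dosages are mean-imputed, preserving the column mean", {
  d <- c(0, 2, NA, 2)   # observed mean 4/3
  enc <- encode_genotypes(d, "additive")
  expect_equal(enc[3], 4 / 3)
  expect_equal(mean(enc), mean(d, na.rm = TRUE))
  # piecewise-linear dominance map at the imputed dosage 4/3
  expect_equal(encode_genotypes(d, "dominance")[3], 1)
  expect_equal(encode_genotypes(d, "overdominance")[3], 1 - abs(4 / 3 - 1))
})

test_that("invalid dosages are rejected", {
  expect_error(encode_genotypes(c(0, 3), "additive"), "0, 1, 2 or NA")
  expect_error(encode_genotypes(c(0, 1), "codominance"))
})

test_that("compute_maf matches hand-computed frequencies and is symmetric", {
  expect_equal(compute_maf(25, 50, 25), 0.5)
  expect_equal(compute_maf(100, 0, 0), 0)
  set.seed(7)
  for (i in 1:20) {
    cnt <- sample(0:500, 3)
    if (sum(cnt) == 0) cnt <- c(1, 0, 0)
    expect_equal(compute_maf(cnt[1], cnt[2], cnt[3]),
                 compute_maf(cnt[3], cnt[2], cnt[1]))
    expect_lte(compute_maf(cnt[1], cnt[2], cnt[3]), 0.5)
  }
  expect_error(compute_maf(0, 0, 0), "zero")
})

test_that("qc_filter applies the three rules in order on a countable fixture", {
  # 10 markers: 2 on X, 1 monomorphic, 1 at MAF 0.005 -> 6 retained (2/1/1)
  n <- 1000
  set.seed(8)
  mk_dos <- function(maf) stats::rbinom(n, 2, maf)
  dos <- cbind(
    mk_dos(0.3), mk_dos(0.3),                  # the two X markers
    rep(0, n),                                  # monomorphic
    c(rep(1, 10), rep(0, n - 10)),              # MAF 10/2000 = 0.005
    mk_dos(0.2), mk_dos(0.25), mk_dos(0.3),
    mk_dos(0.35), mk_dos(0.4), mk_dos(0.45)
  )
  markers <- data.frame(
    snp_id = sprintf("q%02d", 1:10),
    chr = c("X", "30", rep("5", 8)),
    pos = 1:10 * 1000, allele_a = "A", allele_b = "B",
    stringsAsFactors = FALSE)
  gm <- genotype_matrix(dos, sprintf("i%04d", 1:n), markers)
  qc <- qc_filter(gm, maf_min = 0.01)
  expect_equal(ncol(qc$gm$dosages), 6)
  expect_equal(qc$report$rule, c("sex_chromosome", "monomorphic", "low_maf"))
  expect_equal(qc$report$n_removed, c(2L, 1L, 1L))
  expect_equal(qc$report$n_retained, c(8L, 7L, 6L))
})

test_that("the MAF boundary retains exactly-1% markers and drops 0.9%", {
  n <- 1000
  dos <- cbind(
    c(rep(1, 20), rep(0, n - 20)),   # MAF 0.010 -> retained
    c(rep(1, 18), rep(0, n - 18)),   # MAF 0.009 -> removed
    c(rep(1, 500), rep(0, 500))      # comfortably polymorphic
  )
  markers <- data.frame(snp_id = c("at", "below", "ok"), chr = "1",
                        pos = c(1, 2, 3) * 100, allele_a = "A",
                        allele_b = "B", stringsAsFactors = FALSE)
  gm <- genotype_matrix(dos, sprintf("i%04d", 1:n), markers)
  qc <- qc_filter(gm, maf_min = 0.01)
  expect_setequal(qc$gm$markers$snp_id, c("at", "ok"))
})

test_that("qc_filter is idempotent and errors on an emptied panel", {
  set.seed(9)
  gm <- rand_gm(50, 20, maf = c(0.02, 0.5), miss_rate = 0.05,
                chr = c("X", rep("3", 19)))
  once <- qc_filter(gm)
  twice <- qc_filter(once$gm)
  expect_equal(twice$gm$dosages, once$gm$dosages)
  expect_equal(sum(twice$report$n_removed), 0)

  mono <- genotype_matrix(matrix(0, 5, 2), paste0("i", 1:5),
                          data.frame(snp_id = c("a", "b"), chr = "1",
                                     pos = c(1, 2), allele_a = "A",
                                     allele_b = "B"))
  expect_error(qc_filter(mono), "empty")
})
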