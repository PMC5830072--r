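# Synthetic-data generator: determinism, allele-frequency behaviour,
# family structure, planted QTLs, phenotype model.

test_that("identical configurations reproduce bitwise-identical datasets", {
  cfg <- sim_config(n_sires = 10, offspring_per_sire = 4, n_snps = 50,
                    qtl_specs = list(qtl_spec(5, "recessive", 1)),
                    seed = 81)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$gm$dosages, d2$gm$dosages)
  expect_identical(d1$y, d2$y)
  d3 <- simulate_dataset(sim_config(10, 4, 50,
                                    qtl_specs = list(qtl_spec(5, "recessive", 1)),
                                    seed = 82))
  expect_false(identical(d1$gm$dosages, d3$gm$dosages))
})

test_that("at p = 0.5, unrelated mode, genotype classes follow Hardy-Weinberg", {
  cfg <- sim_config(n_sires = 4000, offspring_per_sire = 1, n_snps = 8,
                    maf_low = 0.5, maf_high = 0.5, seed = 83)
  gm <- simulate_genotypes(cfg)
  n <- 4000
  for (j in 1:8) {
    cnt <- genotype_counts(gm$dosages[, j])
    # 3 binomial standard errors around 0.25 / 0.50 / 0.25
    expect_lt(abs(cnt[["n_AA"]] / n - 0.25), 3 * sqrt(0.25 * 0.75 / n))
    expect_lt(abs(cnt[["n_AB"]] / n - 0.50), 3 * sqrt(0.50 * 0.50 / n))
    expect_lt(abs(cnt[["n_BB"]] / n - 0.25), 3 * sqrt(0.25 * 0.75 / n))
  }
})

test_that("empirical allele frequencies track the drawn frequencies", {
  cfg <- sim_config(n_sires = 500, offspring_per_sire = 1, n_snps = 2000,
                    maf_low = 0.05, maf_high = 0.5, seed = 84)
  gm <- simulate_genotypes(cfg)
  p <- attr(gm, "allele_freq")
  emp <- colMeans(gm$dosages) / 2
  # family-wise 99.9% binomial band on 2n allele draws: every marker inside
  m <- 2000
  half_width <- stats::qnorm(1 - 5e-4 / m) * sqrt(p * (1 - p) / (2 * 500))
  expect_true(all(abs(emp - p) <= half_width))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(10, 1, 50, maf_low = 0, maf_high = 0.5), "maf")
  expect_error(sim_config(10, 1, 50, maf_low = 0.3, maf_high = 0.2), "maf")
  expect_error(sim_config(10, 1, 50, maf_high = 0.6), "maf")
  expect_error(sim_config(10, 1, 50, sigma_e2 = 0), "sigma_e2")
  expect_error(sim_config(10, 1, 50,
                          qtl_specs = list(qtl_spec(51, "additive", 1))),
               "exceeds")
})

test_that("plant_qtls follows the coding maps exactly", {
  set.seed(85)
  gm <- rand_gm(200, 10)
  expect_equal(plant_qtls(gm, list()), rep(0, 200))

  b <- 1.7
  g_dom <- plant_qtls(gm, list(qtl_spec(4, "dominance", b)))
  d <- gm$dosages[, 4]
  expect_equal(mean(g_dom[d >= 1]) - mean(g_dom[d == 0]), b)

  g_od <- plant_qtls(gm, list(qtl_spec(4, "overdominance", b)))
  expect_equal(unique(g_od[d == 0]), unique(g_od[d == 2]))
  expect_equal(unique(g_od[d == 1]) - unique(g_od[d == 0]), b)

  # additive QTLs accumulate
  g2 <- plant_qtls(gm, list(qtl_spec(1, "additive", 1),
                            qtl_spec(2, "additive", -0.5)))
  expect_equal(g2, unname(gm$dosages[, 1] - 0.5 * gm$dosages[, 2]))
  expect_error(plant_qtls(gm, list(qtl_spec(11, "additive", 1))),
               "out of range")
})

test_that("a residual-only model yields the residual variance", {
  # pooled chi-square pivot over replicates: sum of (n-1) var(y) / sigma_e2
  # is chi-square with R(n-1) df when y is pure N(0, sigma_e2) noise
  set.seed(86)
  n <- 400
  reps <- 5
  ss <- 0
  for (r in 1:reps) {
    gm <- rand_gm(n, 50)
    ph <- simulate_phenotypes(gm, list(), sigma_u2 = 0, sigma_e2 = 2.5,
                              seed = 860 + r)
    ss <- ss + (n - 1) * stats::var(ph$y)
    if (r == 1) expect_equal(nrow(ph$truth), 0)
  }
  df <- reps * (n - 1)
  band <- ss / stats::qchisq(c(0.995, 0.005), df)
  expect_gt(2.5, band[1])
  expect_lt(2.5, band[2])
})

test_that("duplicated individuals receive perfectly correlated polygenic draws", {
  set.seed(87)
  gm <- rand_gm(40, 300)
  gm$dosages[2, ] <- gm$dosages[1, ]
  ph1 <- simulate_phenotypes(gm, list(), sigma_u2 = 1, sigma_e2 = 1e-4,
                             seed = 87)
  # with negligible residual, y is essentially u: duplicates coincide
  expect_equal(unname(ph1$y[1]), unname(ph1$y[2]), tolerance = 0.05)
})

test_that("the truth table records planted QTLs with frequencies summing to 1", {
  cfg <- sim_config(n_sires = 50, offspring_per_sire = 4, n_snps = 100,
                    qtl_specs = list(qtl_spec(10, "dominance", 1.2),
                                     qtl_spec(90, "overdominance", -0.8)),
                    seed = 88)
  ds <- simulate_dataset(cfg)
  expect_equal(nrow(ds$truth), 2)
  expect_equal(ds$truth$model, c("dominance", "overdominance"))
  expect_equal(ds$truth$freq_AA + ds$truth$freq_AB + ds$truth$freq_BB,
               c(1, 1))
})

test_that("half-sib families are more related within than across", {
  for (seed in c(89, 90)) {
    cfg <- sim_config(n_sires = 12, offspring_per_sire = 8, n_snps = 1000,
                      seed = seed)
    gm <- simulate_genotypes(cfg)
    G <- compute_grm(gm)
    fam <- attr(gm, "sire")
    ut <- upper.tri(G$g)
    within <- mean(G$g[outer(fam, fam, "==") & ut])
    across <- mean(G$g[outer(fam, fam, "!=") & ut])
    expect_gt(within, across)
  }
})
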