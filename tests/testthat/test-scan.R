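# Step-2 score tests against the frozen null covariance.

# small fitted instance shared across tests
make_fit <- function(n = 40, m = 150, seed = 41, h2 = 0.4) {
  set.seed(seed)
  gm <- rand_gm(n, m)
  G <- compute_grm(gm)
  y <- drop(chol(h2 * G$g + (1 - h2) * diag(n)) %*% stats::rnorm(n))
  list(gm = gm, G = G, y = y, nf = fit_null(y, G = G))
}

test_that("snp_test reproduces the dense two-step statistic on a fixture", {
  f <- make_fit(n = 20, m = 80, seed = 42)
  for (model in CODING_MODELS) {
    x <- encode_genotypes(f$gm$dosages[, 3], model)
    got <- snp_test(x, f$nf)
    want <- dense_two_step(f$y, f$nf$X, x, f$G$g,
                           f$nf$vc$sigma_u2, f$nf$vc$sigma_e2)
    expect_equal(got$z, want$z, tolerance = 1e-6)
    expect_equal(got$beta, want$beta, tolerance = 1e-6)
    expect_equal(got$se, want$se, tolerance = 1e-6)
    expect_equal(got$z, got$beta / got$se, tolerance = 1e-10)
    expect_equal(got$p_raw, 2 * stats::pnorm(-abs(got$z)))
  }
})

test_that("the score statistic approximates the joint GLS Wald statistic", {
  f <- make_fit(n = 50, m = 200, seed = 43)
  for (j in c(2, 7, 11)) {
    x <- encode_genotypes(f$gm$dosages[, j], "dominance")
    got <- snp_test(x, f$nf)
    wald <- dense_joint_wald(f$y, f$nf$X, x, f$G$g,
                             f$nf$vc$sigma_u2, f$nf$vc$sigma_e2)
    expect_equal(got$z, wald, tolerance = 0.02)
  }
})

test_that("a vector orthogonal to the residual under V0^-1 gives z = 0", {
  f <- make_fit(n = 30, m = 100, seed = 44)
  r <- f$nf$residuals
  set.seed(1)
  x <- stats::rnorm(30)
  x <- x - mean(x)
  # project out the V0^-1 component along r using a centred direction, so
  # the result stays mean-zero and survives snp_test's internal centring
  vir <- v0_solve(f$nf, r)
  rc <- r - mean(r)
  x <- x - rc * drop(crossprod(x, vir) / crossprod(rc, vir))
  expect_equal(mean(x), 0, tolerance = 1e-12)
  got <- snp_test(x, f$nf)
  expect_equal(got$z, 0, tolerance = 1e-8)
  expect_equal(got$p_raw, 1, tolerance = 1e-8)
})

test_that("with sigma_u2 = 0 the statistic collapses to the OLS slope z", {
  f <- make_fit(n = 50, m = 150, seed = 45)
  nf0 <- f$nf
  nf0$vc$sigma_u2 <- 0
  nf0$vc$sigma_e2 <- 1.3
  # intercept-only design: recompute the GLS residuals for V0 = I s2,
  # which are just deviations from the mean
  nf0$residuals <- f$y - mean(f$y)
  x <- encode_genotypes(f$gm$dosages[, 5], "additive")
  xc <- x - mean(x)
  yc <- f$y - mean(f$y)
  z_ols <- sum(xc * yc) / (sqrt(1.3) * sqrt(sum(xc^2)))
  expect_equal(snp_test(x, nf0)$z, z_ols, tolerance = 1e-8)
})

test_that("constant coded vectors are flagged untestable, not errors", {
  f <- make_fit(n = 30, m = 100, seed = 46)
  got <- snp_test(rep(1, 30), f$nf)
  expect_true(got$untestable)
  expect_true(is.na(got$z))
  # a marker with no BB class is untestable under the recessive coding
  gm <- f$gm
  gm$dosages[, 1] <- c(rep(0, 15), rep(1, 15))
  sc <- genome_scan(gm, f$y, f$nf, models = "recessive")
  row <- sc$results[sc$results$snp_id == gm$markers$snp_id[1] &
                      sc$results$model == "recessive", ]
  expect_true(row$untestable)
  expect_true(is.na(row$z))
})

test_that("genome_scan equals per-marker snp_test and covers all models", {
  f <- make_fit(n = 35, m = 60, seed = 47)
  sc <- genome_scan(f$gm, f$y, f$nf)
  expect_setequal(unique(sc$results$model), CODING_MODELS)
  expect_equal(nrow(sc$results), 60 * 4)
  for (j in c(1, 17, 42)) {
    for (model in CODING_MODELS) {
      x <- encode_genotypes(f$gm$dosages[, j], model)
      want <- snp_test(x, f$nf)
      row <- sc$results[sc$results$snp_id == f$gm$markers$snp_id[j] &
                          sc$results$model == model, ]
      expect_equal(row$z, want$z, tolerance = 1e-10)
      expect_equal(row$beta, want$beta, tolerance = 1e-10)
    }
  }
})

test_that("the additive model is co-computed even when not requested", {
  f <- make_fit(n = 30, m = 40, seed = 48)
  sc <- genome_scan(f$gm, f$y, f$nf, models = "dominance")
  expect_setequal(unique(sc$results$model), c("dominance", "additive"))
})

test_that("permuting marker order permutes scan results identically", {
  f <- make_fit(n = 30, m = 50, seed = 49)
  sc1 <- genome_scan(f$gm, f$y, f$nf, models = "dominance")
  perm <- sample(50)
  gm2 <- genotype_matrix(f$gm$dosages[, perm], f$gm$ids,
                         f$gm$markers[perm, ])
  sc2 <- genome_scan(gm2, f$y, f$nf, models = "dominance")
  r1 <- sc1$results[sc1$results$model == "dominance", ]
  r2 <- sc2$results[sc2$results$model == "dominance", ]
  r2 <- r2[match(r1$snp_id, r2$snp_id), ]
  expect_equal(r1$z, r2$z)
  expect_equal(r1$p_gc, r2$p_gc)
})

test_that("id misalignment between genotypes and null fit is a hard error", {
  f <- make_fit(n = 30, m = 40, seed = 50)
  gm2 <- f$gm
  gm2$ids <- rev(gm2$ids)
  rownames(gm2$dosages) <- gm2$ids
  expect_error(genome_scan(gm2, f$y, f$nf), "ids")
})

test_that("marker genotype counts in scan output match compute_maf inputs", {
  f <- make_fit(n = 40, m = 30, seed = 51)
  sc <- genome_scan(f$gm, f$y, f$nf, models = "dominance")
  r <- sc$results[sc$results$model == "dominance", ]
  for (j in c(3, 12)) {
    cnt <- genotype_counts(f$gm$dosages[, j])
    row <- r[r$snp_id == f$gm$markers$snp_id[j], ]
    expect_equal(c(row$n_AA, row$n_AB, row$n_BB), unname(cnt))
    expect_equal(row$maf,
                 unname(compute_maf(cnt[["n_AA"]], cnt[["n_AB"]],
                                    cnt[["n_BB"]])))
  }
})
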