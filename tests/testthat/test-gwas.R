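test_that("qc_filter applies strict MAF and missingness boundaries", {
  # 10 SNPs with hand-enumerated frequencies over 10 lines
  d <- matrix(0, 10, 10)
  d[1, 1] <- 1                 # f = 0.05  -> MAF exactly 0.05, removed
  d[1:2, 2] <- 1               # f = 0.10  -> kept
  d[, 3] <- 1                  # f = 0.50  -> kept
  d[1:9, 4] <- 2; d[10, 4] <- 1  # f = 0.95 -> MAF 0.05, removed
  d[1:3, 5] <- 2               # f = 0.30  -> kept
  # column 6 monomorphic     -> MAF 0, removed
  d[1:2, 7] <- c(1, 1); d[3:4, 7] <- NA  # 20% missing, removed (strict)
  d[1, 8] <- 1; d[2, 8] <- NA            # 10% missing, MAF 1/18, kept
  d[1:5, 9] <- 2               # f = 0.5 -> kept
  d[1, 10] <- 2                # f = 0.1 -> kept
  g <- toy_genotypes(d)
  kept <- qc_filter(g, maf_min = 0.05, missing_max = 0.20)$snps$snp_id
  expect_equal(kept, g$snps$snp_id[c(2, 3, 5, 8, 9, 10)])
})

test_that("qc_filter warns instead of erroring when nothing survives", {
  g <- toy_genotypes(matrix(c(0, 0, 0, 0), 4, 1))
  expect_warning(out <- qc_filter(g), "every SNP")
  expect_equal(ncol(out$dosage), 0L)
})

test_that("GRM matches the hand-standardised 3x3 oracle", {
  d <- matrix(c(0, 1, 2,
                2, 2, 0), nrow = 3)
  g <- toy_genotypes(d)
  f <- colMeans(d) / 2
  Z <- sweep(sweep(d, 2, 2 * f), 2, sqrt(2 * f * (1 - f)), "/")
  expect_equal(compute_grm(g), structure(Z %*% t(Z) / 2,
                                         dimnames = list(g$line_ids,
                                                         g$line_ids)))
})

test_that("identical lines share diagonal and off-diagonal GRM entries", {
  d <- rbind(c(0, 2, 1, 1), c(0, 2, 1, 1), c(2, 0, 1, 0))
  g <- toy_genotypes(d)
  K <- compute_grm(g)
  expect_equal(K[1, 2], K[1, 1])
  expect_equal(K[2, 1], K[2, 2])
})

test_that("GRM diagonal averages one on a large random panel", {
  g <- simulate_genotypes(2000, 300, seed = 31)
  K <- compute_grm(g)
  expect_lt(abs(mean(diag(K)) - 1), 0.05)
})

test_that("monomorphic SNPs are refused by the GRM with their name", {
  g <- toy_genotypes(cbind(c(0, 1, 1), c(2, 2, 2)))
  expect_error(compute_grm(g), g$snps$snp_id[2])
})

test_that("null REML recovers absence and presence of heritability", {
  g <- simulate_genotypes(1000, 1500, ld_rho = 0.2, seed = 41)
  eig <- grm_eigen(compute_grm(g))
  set.seed(1)
  y0 <- rnorm(1000)
  vc0 <- fit_null_lmm(y0, eig)
  expect_lt(vc0$h2, 0.1)

  cfg <- study_config(populations = data.frame(population = "P1",
                                               n_lines = 1000),
                      environments = "E1", n_snps = 1500, seed = 43)
  st <- simulate_study(cfg)  # h2(GPP) = 0.5
  g2 <- st$genotypes$P1_E1
  vc <- fit_null_lmm(as.vector(phenotype_vector(st, "P1_E1", "GPP")),
                     grm_eigen(compute_grm(g2)))
  expect_gt(vc$h2, 0.4)
  expect_lt(vc$h2, 0.6)
  expect_equal(vc$h2, vc$sigma_g2 / (vc$sigma_g2 + vc$sigma_e2))
})

test_that("identity GRM is flagged non-identifiable with h2 = 0", {
  K <- diag(50)
  set.seed(2)
  expect_warning(vc <- fit_null_lmm(rnorm(50), K), "identifiable")
  expect_equal(vc$h2, 0)
})

test_that("with sigma_g2 = 0 the scan reduces to least squares", {
  set.seed(3)
  g <- simulate_genotypes(200, 30, seed = 51)
  y <- rnorm(200)
  s2 <- var(y)
  vc <- structure(list(sigma_g2 = 0, sigma_e2 = s2, h2 = 0),
                  class = "variance_components")
  res <- mlma_scan(g, y, vc)
  X <- g$dosage
  for (j in c(1, 15, 30)) {
    fit <- lm(y ~ X[, j])
    expect_equal(res$BETA[j], unname(coef(fit)[2]), tolerance = 1e-8)
    # fixed-variance GLS standard error: sigma_e known, not re-estimated
    xtx <- sum((X[, j] - mean(X[, j]))^2)
    expect_equal(res$SE[j], sqrt(s2 / xtx), tolerance = 1e-8)
    expect_equal(res$P[j],
                 2 * pnorm(-abs(res$BETA[j] / res$SE[j])), tolerance = 1e-10)
  }
})

test_that("fixed covariates are projected out of the scan", {
  set.seed(9)
  g <- simulate_genotypes(150, 10, seed = 73)
  C <- cbind(rnorm(150))
  y <- 2 * C[, 1] + 0.5 * g$dosage[, 4] + rnorm(150)
  vc <- structure(list(sigma_g2 = 0, sigma_e2 = 1, h2 = 0),
                  class = "variance_components")
  res <- mlma_scan(g, y, vc, grm_eigen(diag(150)), covariates = C)
  for (j in c(4, 9)) {
    fit <- lm(y ~ C + g$dosage[, j])
    expect_equal(res$BETA[j], unname(coef(fit)[3]), tolerance = 1e-8)
  }
})

test_that("a strong causal SNP reaches genome-wide significance", {
  cfg <- study_config(populations = data.frame(population = "P1",
                                               n_lines = 1000),
                      environments = "E1", n_snps = 1000,
                      n_causal = c(GPP = 2, KGW = 2, TP = 2), seed = 53)
  st <- simulate_study(cfg)
  g <- st$genotypes$P1_E1
  eig <- grm_eigen(compute_grm(g))
  y <- as.vector(phenotype_vector(st, "P1_E1", "GPP"))
  vc <- fit_null_lmm(y, eig)
  res <- mlma_scan(g, y, vc, eig)
  planted <- st$truth$component_effects$GPP$snp_id
  expect_true(all(res$P[match(planted, res$SNP)] < 1e-6))
})

test_that("null SNPs reject at the nominal rate with uniform p-values", {
  cfg <- study_config(populations = data.frame(population = "P1",
                                               n_lines = 800),
                      environments = "E1", n_snps = 1000, ld_rho = 0,
                      n_causal = c(GPP = 0, KGW = 0, TP = 0),
                      n_polygenic = 0, n_direct = 0,
                      residual_sd = c(GPP = 10, KGW = 1, TP = 1),
                      seed = 59)
  st <- simulate_study(cfg)
  g <- st$genotypes$P1_E1
  eig <- grm_eigen(compute_grm(g))
  y <- as.vector(phenotype_vector(st, "P1_E1", "GPP"))
  vc <- fit_null_lmm(y, eig)
  res <- mlma_scan(g, y, vc, eig)
  expect_gt(mean(res$P < 0.05), 0.03)
  expect_lt(mean(res$P < 0.05), 0.07)
  ks <- suppressWarnings(stats::ks.test(res$P, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("scan results are invariant under line reordering", {
  g <- simulate_genotypes(150, 40, seed = 61)
  set.seed(4)
  y <- rnorm(150) + g$dosage[, 5]
  eig <- grm_eigen(compute_grm(g))
  vc <- fit_null_lmm(y, eig)
  res1 <- mlma_scan(g, y, vc, eig)

  # same variance components, permuted lines: the GLS fit is invariant
  perm <- sample(150)
  g2 <- genotype_matrix(g$dosage[perm, ], g$snps, g$line_ids[perm])
  res2 <- mlma_scan(g2, y[perm], vc, grm_eigen(compute_grm(g2)))
  expect_equal(res2$BETA, res1$BETA, tolerance = 1e-8)
  expect_equal(res2$SE, res1$SE, tolerance = 1e-8)
})

test_that("zero-variance SNPs are skipped with a log entry", {
  g <- simulate_genotypes(100, 10, seed = 67)
  g$dosage[, 3] <- 1  # constant dosage
  set.seed(5)
  y <- rnorm(100)
  vc <- structure(list(sigma_g2 = 0, sigma_e2 = 1, h2 = 0),
                  class = "variance_components")
  expect_message(res <- mlma_scan(g, y, vc, grm_eigen(diag(100))),
                 "skipped")
  expect_false(g$snps$snp_id[3] %in% res$SNP)
  expect_equal(attr(res, "skipped"), g$snps$snp_id[3])
})

test_that("run_gwas drops lines with missing phenotypes", {
  cfg <- study_config(populations = data.frame(population = "P1",
                                               n_lines = 120),
                      environments = "E1", n_snps = 60,
                      n_causal = c(GPP = 2, KGW = 2, TP = 2), n_direct = 1,
                      n_polygenic = 10, min_causal_gap = 5, seed = 71)
  st <- simulate_study(cfg)
  ph <- st$phenotypes
  ph$value[ph$trait == "GPP"][1:10] <- NA
  res <- run_gwas(st$genotypes$P1_E1, ph, "GPP", "P1_E1")
  expect_equal(unique(res$N), 110)
  expect_s3_class(attr(res, "vc"), "variance_components")
})
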