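# shared fixtures, built in code at test time

# tiny genotype matrix with explicit dosages
toy_genotypes <- function(dosage, chrom = NULL, pos = NULL) {
  m <- ncol(dosage)
  if (is.null(chrom)) chrom <- rep(1L, m)
  if (is.null(pos)) pos <- seq_len(m) * 100L
  genotype_matrix(dosage,
                  data.frame(chrom = chrom, pos = pos,
                             allele_ref = "A", allele_alt = "G",
                             stringsAsFactors = FALSE),
                  sprintf("L%02d", seq_len(nrow(dosage))))
}

# instrument set built from bare vectors
make_instruments <- function(bx, sex, px, by, sey, py,
                             exposure = "GPP", outcome = "YD") {
  k <- length(bx)
  instrument_set(exposure, outcome, data.frame(
    SNP = sprintf("chr01_%d", seq_len(k) * 1000L),
    CHR = 1L, POS = seq_len(k) * 1000L,
    BETA_X = bx, SE_X = sex, P_X = px,
    BETA_Y = by, SE_Y = sey, P_Y = py,
    stringsAsFactors = FALSE))
}

# summary-stat rows for meta tests
make_stats <- function(beta, se, snp = "chr01_100", n = 500) {
  k <- length(beta)
  data.frame(SNP = snp, CHR = 1L, POS = 100L, A1 = "G", A2 = "A",
             BETA = beta, SE = se, P = pmax(2 * pnorm(-abs(beta / se)),
                                            .Machine$double.xmin),
             N = n, stringsAsFactors = FALSE)
}

# a minimal meta-stat table from explicit columns
make_meta <- function(snp, p, beta = 1, se = 0.1, chr = 1L,
                      pos = seq_along(snp) * 1000L, trait = "GPP") {
  data.frame(SNP = snp, CHR = chr, POS = pos, A1 = "G", A2 = "A",
             BETA = beta, SE = se, P = p, N = 1000L,
             K = 2L, Q = 0, DF = 1L, I2 = 0, MODEL = "fixed",
             TRAIT = trait, stringsAsFactors = FALSE)
}

# brute-force enumeration of the two-SNP haplotype copying process:
# P(a1, a2) = P(a1) * [rho 1{a2 = a1} + (1 - rho) f2^a2 (1-f2)^(1-a2)];
# returns the dosage-level r^2 implied by two iid haplotypes per line
copying_process_r2 <- function(f1, f2, rho) {
  p <- matrix(0, 2, 2)  # allele of snp1 x allele of snp2
  for (a1 in 0:1) for (a2 in 0:1) {
    p1 <- if (a1 == 1) f1 else 1 - f1
    pf <- if (a2 == 1) f2 else 1 - f2
    p[a1 + 1, a2 + 1] <- p1 * (rho * (a2 == a1) + (1 - rho) * pf)
  }
  m1 <- sum(p[2, ]); m2 <- sum(p[, 2])
  cov_h <- p[2, 2] - m1 * m2
  # dosage = sum of two independent haplotypes -> same correlation
  (cov_h / sqrt(m1 * (1 - m1) * m2 * (1 - m2)))^2
}

# two-population single-environment design: two independent datasets,
# the layout used for the simulation-based validation studies
two_pop_config <- function(n_lines = 1000, n_snps = 5000, seed = 1, ...) {
  study_config(
    populations = data.frame(population = c("P1", "P2"),
                             n_lines = n_lines),
    environments = "E1",
    n_snps = n_snps, seed = seed, ...)
}

# per-dataset association stats at chosen SNPs only (GRM still uses the
# full panel), as a fast path for truth-set MR checks; pass a precomputed
# grm_eigen to amortise the decomposition across traits
scan_at_loci <- function(study, dataset_id, trait, snp_ids, eig = NULL) {
  g <- study$genotypes[[dataset_id]]
  if (is.null(eig)) eig <- grm_eigen(compute_grm(g))
  y <- phenotype_vector(study, dataset_id, trait)
  y <- as.vector(y[match(g$line_ids, names(y))])
  vc <- fit_null_lmm(y, eig)
  gs <- g
  j <- match(snp_ids, g$snps$snp_id)
  gs$dosage <- g$dosage[, j, drop = FALSE]
  gs$snps <- g$snps[j, , drop = FALSE]
  mlma_scan(gs, y, vc, eig, trait = trait, dataset_id = dataset_id)
}
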