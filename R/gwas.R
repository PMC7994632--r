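#' QC-filter SNPs on MAF and missingness
#'
#' Retains SNPs with minor allele frequency strictly greater than `maf_min`
#' and missing fraction strictly lower than `missing_max` (the "MAF > x,
#' missing rate < y" convention). The line set is unchanged.
#'
#' @param g a [genotype_matrix()].
#' @param maf_min MAF threshold in `[0, 0.5)`.
#' @param missing_max missing-rate threshold in `[0, 1]`.
#' @return the filtered [genotype_matrix()]; a warning (not an error) is
#'   raised if no SNP survives.
#' @export
qc_filter <- function(g, maf_min = 0.05, missing_max = 0.20) {
  if (maf_min < 0 || maf_min >= 0.5) stopf("maf_min must be in [0, 0.5)")
  if (missing_max < 0 || missing_max > 1) stopf("missing_max must be in [0, 1]")
  # strict inequalities, decided at 1e-9 so count-derived rates that land
  # exactly on a threshold are not kept through representation noise
  keep <- (snp_maf(g) - maf_min) > 1e-9 &
    (missing_max - snp_missing_rate(g)) > 1e-9
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) warnf("qc_filter removed every SNP")
  subset_snps(g, which(keep))
}

subset_snps <- function(g, j) {
  genotype_matrix(g$dosage[, j, drop = FALSE], g$snps[j, , drop = FALSE],
                  g$line_ids)
}

subset_lines <- function(g, i) {
  genotype_matrix(g$dosage[i, , drop = FALSE], g$snps, g$line_ids[i])
}

# mean-impute missing dosages per SNP (the GRM / scan convention)
impute_dosage <- function(g) {
  d <- g$dosage
  if (!anyNA(d)) return(d)
  mu <- colMeans(d, na.rm = TRUE)
  nas <- which(is.na(d), arr.ind = TRUE)
  d[nas] <- mu[nas[, 2]]
  d
}

#' Genomic relationship matrix
#'
#' VanRaden-style GRM: `Z Z' / m` where `Z` is the column-standardised
#' dosage matrix, `Z_ij = (d_ij - 2 f_j) / sqrt(2 f_j (1 - f_j))`, and `m`
#' the SNP count. Missing dosages are mean-imputed per SNP. The mean
#' diagonal is ~1 for Hardy-Weinberg-like panels.
#'
#' @param g a [genotype_matrix()]; no SNP may be monomorphic.
#' @return symmetric lines x lines matrix with line ids as dimnames.
#' @export
compute_grm <- function(g) {
  d <- impute_dosage(g)
  f <- colMeans(d) / 2
  mono <- f <= 0 | f >= 1
  if (any(mono))
    stopf("monomorphic SNP(s) in GRM input: %s",
          paste(g$snps$snp_id[mono][seq_len(min(5, sum(mono)))],
                collapse = ", "))
  Z <- sweep(sweep(d, 2, 2 * f), 2, sqrt(2 * f * (1 - f)), "/")
  K <- tcrossprod(Z) / ncol(Z)
  dimnames(K) <- list(g$line_ids, g$line_ids)
  K
}

#' Eigendecomposition of a GRM
#'
#' Cached decomposition reused by [fit_null_lmm()] and [mlma_scan()] so the
#' O(n^3) step is paid once per dataset.
#'
#' @param K symmetric positive semi-definite relatedness matrix.
#' @param tol eigenvalues below `-tol` trigger a decomposition error.
#' @return list of class `grm_eigen` with `values` and `vectors`.
#' @export
grm_eigen <- function(K, tol = 1e-8) {
  e <- eigen(K, symmetric = TRUE)
  if (min(e$values) < -tol * max(1, abs(max(e$values))))
    stopf("GRM is not positive semi-definite (min eigenvalue %.3g)",
          min(e$values))
  e$values <- pmax(e$values, 0)
  structure(list(values = e$values, vectors = e$vectors,
                 line_ids = rownames(K)), class = "grm_eigen")
}

as_grm_eigen <- function(x) {
  if (inherits(x, "grm_eigen")) x else grm_eigen(x)
}

#' REML fit of the null polygenic model
#'
#' Fits `y = mu + g + e` with `g ~ N(0, sigma_g^2 K)` and
#' `e ~ N(0, sigma_e^2 I)` by profiling the scale analytically and
#' maximising the restricted likelihood over `h2 = sigma_g^2 /
#' (sigma_g^2 + sigma_e^2)` on `[0, 1]` in the eigenbasis of the GRM.
#'
#' @param y complete named phenotype vector for the analysed lines.
#' @param grm relatedness matrix or a precomputed [grm_eigen()].
#' @param covariates optional numeric matrix of fixed covariates (one row
#'   per line); an intercept is always included.
#' @return list of class `variance_components`: `sigma_g2`, `sigma_e2`,
#'   `h2`, `loglik`. If the GRM eigenvalues are all equal (e.g. identity)
#'   the likelihood is flat in `h2`; the fit returns `h2 = 0` with a
#'   non-identifiability warning.
#' @export
fit_null_lmm <- function(y, grm, covariates = NULL) {
  eig <- as_grm_eigen(grm)
  n <- length(y)
  if (n != length(eig$values))
    stopf("phenotype length %d does not match GRM order %d", n,
          length(eig$values))
  if (anyNA(y)) stopf("fit_null_lmm requires a complete phenotype vector")
  lam <- eig$values
  ys <- as.vector(crossprod(eig$vectors, y))
  X <- cbind(`(Intercept)` = rep(1, n), covariates)
  Xs <- crossprod(eig$vectors, X)
  p <- ncol(Xs)

  restricted_ll <- function(h2) {
    d <- pmax(h2 * lam + (1 - h2), 1e-10)
    w <- 1 / d
    XtWX <- crossprod(Xs, w * Xs)
    beta <- solve(XtWX, crossprod(Xs, w * ys))
    r <- ys - as.vector(Xs %*% beta)
    sig2 <- sum(w * r^2) / (n - p)
    -0.5 * ((n - p) * log(sig2) + sum(log(d)) +
              determinant(XtWX, logarithm = TRUE)$modulus)
  }

  if (diff(range(lam)) < 1e-8) {
    warnf("GRM eigenvalues are constant: h2 is not identifiable; returning h2 = 0")
    h2 <- 0
  } else {
    opt <- optimize(restricted_ll, c(0, 1), maximum = TRUE, tol = 1e-8)
    cand <- c(0, opt$maximum, 1 - 1e-9)
    h2 <- cand[which.max(vapply(cand, restricted_ll, numeric(1)))]
  }
  d <- pmax(h2 * lam + (1 - h2), 1e-10)
  w <- 1 / d
  XtWX <- crossprod(Xs, w * Xs)
  beta <- solve(XtWX, crossprod(Xs, w * ys))
  sig2 <- sum(w * (ys - as.vector(Xs %*% beta))^2) / (n - p)
  structure(list(sigma_g2 = h2 * sig2, sigma_e2 = (1 - h2) * sig2, h2 = h2,
                 loglik = as.numeric(restricted_ll(h2))),
            class = "variance_components")
}

#' EMMAX-style mixed-linear-model association scan
#'
#' Per SNP, generalised least squares of `y` on `[1, dosage]` under
#' `V = sigma_g^2 K + sigma_e^2 I`, with the variance components held
#' fixed at the null-model estimates (the EMMAX/GCTA-MLMA convention) and
#' the system solved in the GRM eigenbasis. Standard errors come from the
#' GLS information matrix; p-values are two-sided normal. Missing dosages
#' are mean-imputed; SNPs with zero dosage variance are skipped and listed
#' in the `skipped` attribute.
#'
#' @param g a [genotype_matrix()] for the analysed lines.
#' @param y complete phenotype vector aligned with `g$line_ids`.
#' @param vc a `variance_components` fit from [fit_null_lmm()] on the same
#'   lines.
#' @param eig optional [grm_eigen()] of the same GRM; computed from
#'   [compute_grm()] when absent.
#' @param covariates optional fixed-covariate matrix (one row per line),
#'   the same one given to [fit_null_lmm()].
#' @param trait,dataset_id optional labels copied into the output.
#' @return data.frame with columns SNP/CHR/POS/A1/A2/BETA/SE/P/N
#'   (A1 = ALT = the dosage-counted effect allele).
#' @export
mlma_scan <- function(g, y, vc, eig = NULL, covariates = NULL,
                      trait = NA_character_, dataset_id = NA_character_) {
  stopifnot(inherits(vc, "variance_components"))
  if (anyNA(y)) stopf("mlma_scan requires a complete phenotype vector")
  n <- length(g$line_ids)
  if (length(y) != n) stopf("phenotype length does not match line count")
  if (is.null(eig)) eig <- grm_eigen(compute_grm(g))

  d <- vc$sigma_g2 * eig$values + vc$sigma_e2
  if (all(d <= 0)) stopf("degenerate variance components")
  w <- 1 / pmax(d, 1e-12)
  U <- eig$vectors
  ys <- as.vector(crossprod(U, y))
  X0 <- cbind(rep(1, n), covariates)
  X0s <- crossprod(U, X0)
  X <- impute_dosage(g)
  keep <- apply(X, 2, var) > 0
  skipped <- g$snps$snp_id[!keep]
  Xs <- crossprod(U, X[, keep, drop = FALSE])

  # weighted Frisch-Waugh: project the nuisance design (intercept +
  # covariates) out of y and every SNP column under the GLS weights
  A <- crossprod(X0s, w * X0s)
  yr <- ys - as.vector(X0s %*% solve(A, crossprod(X0s, w * ys)))
  Xr <- Xs - X0s %*% solve(A, crossprod(X0s, w * Xs))
  sxx <- colSums(w * Xr^2)
  beta <- colSums(w * Xr * yr) / sxx
  se <- sqrt(1 / sxx)
  z <- beta / se
  p <- 2 * pnorm(-abs(z))
  p <- pmax(p, .Machine$double.xmin)  # keep P in (0, 1]

  sn <- g$snps[keep, , drop = FALSE]
  out <- data.frame(SNP = sn$snp_id, CHR = sn$chrom, POS = sn$pos,
                    A1 = sn$allele_alt, A2 = sn$allele_ref,
                    BETA = beta, SE = se, P = p, N = n,
                    stringsAsFactors = FALSE)
  out$TRAIT <- trait
  out$DATASET <- dataset_id
  attr(out, "skipped") <- skipped
  if (length(skipped))
    message(sprintf("mlma_scan: skipped %d zero-variance SNP(s)",
                    length(skipped)))
  rownames(out) <- NULL
  out
}

#' One-dataset GWAS convenience wrapper
#'
#' Applies QC, drops lines with a missing phenotype, builds the GRM,
#' fits the null polygenic model and runs [mlma_scan()].
#'
#' @param g a [genotype_matrix()].
#' @param phenotypes long phenotype data.frame (see [read_phenotypes()]).
#' @param trait,dataset_id which phenotype slice to analyse.
#' @param maf_min,missing_max QC thresholds (see [qc_filter()]).
#' @param eig optional [grm_eigen()] for the full line set; reusable only
#'   when no phenotype is missing.
#' @return the [mlma_scan()] data.frame with the fitted
#'   `variance_components` as attribute `vc`.
#' @export
run_gwas <- function(g, phenotypes, trait, dataset_id, maf_min = 0.05,
                     missing_max = 0.20, eig = NULL) {
  y <- phenotype_vector(phenotypes, dataset_id, trait)
  y <- y[match(g$line_ids, names(y))]
  ok <- !is.na(y)
  if (sum(ok) < 3) stopf("fewer than 3 phenotyped lines for %s/%s",
                         dataset_id, trait)
  g <- qc_filter(g, maf_min, missing_max)
  if (!all(ok)) {
    g <- subset_lines(g, which(ok))
    y <- y[ok]
    eig <- NULL
  }
  if (is.null(eig)) eig <- grm_eigen(compute_grm(g))
  vc <- fit_null_lmm(as.vector(y), eig)
  out <- mlma_scan(g, as.vector(y), vc, eig, trait = trait,
                   dataset_id = dataset_id)
  attr(out, "vc") <- vc
  out
}
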