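#' Cochran's Q heterogeneity test
#'
#' `Q = sum w_i (b_i - b_FE)^2` with inverse-variance weights
#' `w_i = 1/se_i^2` and `b_FE` the fixed-effect estimate; `df = k - 1`;
#' the p-value is the upper chi-square tail; `I2 = max(0, (Q - df)/Q)`
#' (0 when `Q = 0`). With a single estimate `Q = 0`, `df = 0` and the
#' undefined p is reported as 1.
#'
#' @param betas,ses equal-length numeric vectors; all `ses > 0`.
#' @return list with `Q`, `df`, `p`, `i2`.
#' @export
cochran_q <- function(betas, ses) {
  if (length(betas) != length(ses)) stopf("betas and ses differ in length")
  if (any(!is.finite(ses) | ses <= 0)) stopf("all ses must be positive")
  k <- length(betas)
  if (k == 1L) return(list(Q = 0, df = 0L, p = 1, i2 = 0))
  w <- 1 / ses^2
  bfe <- sum(w * betas) / sum(w)
  Q <- sum(w * (betas - bfe)^2)
  df <- k - 1L
  list(Q = Q, df = df, p = pchisq(Q, df, lower.tail = FALSE),
       i2 = if (Q > 0) max(0, (Q - df) / Q) else 0)
}

meta_check_input <- function(stats) {
  if (nrow(stats) == 0L) stopf("no studies to combine")
  if (length(unique(stats$SNP)) != 1L)
    stopf("meta input mixes snp ids: %s",
          paste(unique(stats$SNP), collapse = ", "))
  if (any(stats$SE <= 0)) stopf("all SE must be positive")
  invisible(stats)
}

meta_row <- function(stats, beta, se, k, Q, df, i2, model) {
  p <- 2 * pnorm(-abs(beta / se))
  data.frame(SNP = stats$SNP[1], CHR = stats$CHR[1], POS = stats$POS[1],
             A1 = stats$A1[1], A2 = stats$A2[1],
             BETA = beta, SE = se, P = max(p, .Machine$double.xmin),
             N = sum(stats$N), K = k, Q = Q, DF = df, I2 = i2,
             MODEL = model, stringsAsFactors = FALSE)
}

#' Fixed-effect inverse-variance meta-analysis of one SNP
#'
#' Each study is weighted by the inverse of its squared standard error:
#' `beta = sum(w b)/sum(w)`, `se = 1/sqrt(sum w)`, two-sided normal p,
#' with heterogeneity fields from [cochran_q()].
#'
#' @param stats data.frame of per-study rows for a single SNP and trait
#'   (summary-stat columns, see [read_summary_stats()]).
#' @return one-row meta-statistic data.frame (see [read_meta_stats()]).
#' @export
meta_fixed <- function(stats) {
  meta_check_input(stats)
  w <- 1 / stats$SE^2
  beta <- sum(w * stats$BETA) / sum(w)
  se <- 1 / sqrt(sum(w))
  h <- cochran_q(stats$BETA, stats$SE)
  meta_row(stats, beta, se, nrow(stats), h$Q, h$df, h$i2, "fixed")
}

#' DerSimonian-Laird random-effects meta-analysis of one SNP
#'
#' The between-study variance is
#' `tau2 = max(0, (Q - df) / (sum w - sum w^2 / sum w))` with fixed-effect
#' weights `w`; studies are re-weighted as `1/(se^2 + tau2)` and combined
#' as in [meta_fixed()]. When `Q <= df` the method collapses to the
#' fixed-effect result.
#'
#' @param stats per-study rows for one SNP (k >= 2).
#' @return one-row meta-statistic data.frame with `MODEL = "random"`.
#' @export
meta_random <- function(stats) {
  meta_check_input(stats)
  if (nrow(stats) < 2L) stopf("meta_random needs k >= 2 studies")
  w <- 1 / stats$SE^2
  h <- cochran_q(stats$BETA, stats$SE)
  tau2 <- max(0, (h$Q - h$df) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (stats$SE^2 + tau2)
  beta <- sum(ws * stats$BETA) / sum(ws)
  se <- 1 / sqrt(sum(ws))
  out <- meta_row(stats, beta, se, nrow(stats), h$Q, h$df, h$i2, "random")
  attr(out, "tau2") <- tau2
  out
}

# align study alleles to the reference A1/A2; returns BETA with flips
# applied, or NA where the alleles are irreconcilable
align_alleles <- function(a1, a2, ref_a1, ref_a2, beta) {
  same <- a1 == ref_a1 & a2 == ref_a2
  flip <- a1 == ref_a2 & a2 == ref_a1
  out <- ifelse(same, beta, ifelse(flip, -beta, NA_real_))
  out
}

#' Meta-analysis of per-dataset GWAS summary statistics
#'
#' Combines per-SNP statistics across datasets matched on snp id. Alleles
#' are aligned to the first dataset carrying the SNP (sign-flipping BETA
#' when A1/A2 are swapped; irreconcilable alleles drop the SNP with a
#' warning). Each SNP is combined with the fixed-effect model; where
#' `I2 >= i2_switch` the DerSimonian-Laird random-effects model replaces
#' it, recorded in `MODEL`. SNPs present in a subset of datasets are
#' combined over that subset. Significance is strict: `P < alpha`.
#'
#' @param per_dataset_stats list of summary-stat data.frames, one per
#'   dataset.
#' @param trait optional trait label (copied to the output).
#' @param alpha genome-wide significance threshold (default 1e-6).
#' @param i2_switch heterogeneity level at which the random-effects model
#'   takes over (default 0.5).
#' @return list with `meta` (all SNPs) and `significant` (`P < alpha`),
#'   both meta-statistic data.frames sorted by CHR and POS.
#' @export
run_meta_gwas <- function(per_dataset_stats, trait = NA_character_,
                          alpha = 1e-6, i2_switch = 0.5) {
  stopifnot(is.list(per_dataset_stats), length(per_dataset_stats) >= 1)
  k <- length(per_dataset_stats)
  all_snps <- unique(unlist(lapply(per_dataset_stats, `[[`, "SNP")))
  m <- length(all_snps)

  B <- S <- N <- matrix(NA_real_, m, k)
  ref <- NULL
  dropped <- character(0)
  for (i in seq_len(k)) {
    st <- per_dataset_stats[[i]]
    ix <- match(st$SNP, all_snps)
    if (is.null(ref)) {
      ref <- data.frame(SNP = all_snps, CHR = NA_integer_, POS = NA_integer_,
                        A1 = NA_character_, A2 = NA_character_,
                        stringsAsFactors = FALSE)
    }
    new <- is.na(ref$A1[ix])
    ref$CHR[ix[new]] <- st$CHR[new]
    ref$POS[ix[new]] <- st$POS[new]
    ref$A1[ix[new]] <- st$A1[new]
    ref$A2[ix[new]] <- st$A2[new]
    b <- align_alleles(st$A1, st$A2, ref$A1[ix], ref$A2[ix], st$BETA)
    mism <- is.na(b) & !is.na(st$BETA)
    if (any(mism)) dropped <- c(dropped, st$SNP[mism])
    B[ix, i] <- b
    S[ix, i] <- st$SE
    N[ix, i] <- st$N
  }
  if (length(dropped)) {
    dropped <- unique(dropped)
    warnf("dropped %d SNP(s) with irreconcilable alleles (e.g. %s)",
          length(dropped), dropped[1])
    keep <- !all_snps %in% dropped
    B <- B[keep, , drop = FALSE]; S <- S[keep, , drop = FALSE]
    N <- N[keep, , drop = FALSE]; ref <- ref[keep, , drop = FALSE]
    m <- sum(keep)
  }

  W <- 1 / S^2
  sw <- rowSums(W, na.rm = TRUE)
  beta <- rowSums(W * B, na.rm = TRUE) / sw
  se <- 1 / sqrt(sw)
  kk <- rowSums(!is.na(W))
  Q <- rowSums(W * (B - beta)^2, na.rm = TRUE)
  df <- pmax(kk - 1L, 0L)
  i2 <- ifelse(Q > 0, pmax(0, (Q - df) / Q), 0)

  use_re <- i2 >= i2_switch & kk >= 2
  if (any(use_re)) {
    denom <- sw - rowSums(W^2, na.rm = TRUE) / sw
    tau2 <- pmax(0, (Q - df) / denom)
    Ws <- 1 / sweep(S^2, 1, tau2, "+")
    Ws[is.na(W)] <- NA
    sws <- rowSums(Ws, na.rm = TRUE)
    beta_re <- rowSums(Ws * B, na.rm = TRUE) / sws
    se_re <- 1 / sqrt(sws)
    beta[use_re] <- beta_re[use_re]
    se[use_re] <- se_re[use_re]
  }
  p <- pmax(2 * pnorm(-abs(beta / se)), .Machine$double.xmin)

  meta <- data.frame(SNP = ref$SNP, CHR = ref$CHR, POS = ref$POS,
                     A1 = ref$A1, A2 = ref$A2, BETA = beta, SE = se, P = p,
                     N = rowSums(N, na.rm = TRUE), K = kk, Q = Q, DF = df,
                     I2 = i2,
                     MODEL = ifelse(use_re, "random", "fixed"),
                     stringsAsFactors = FALSE)
  meta$TRAIT <- rep(trait, nrow(meta))
  meta <- meta[order(meta$CHR, meta$POS), ]
  rownames(meta) <- NULL
  list(meta = meta, significant = meta[meta$P < alpha, ])
}
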