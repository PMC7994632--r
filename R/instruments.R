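#' Construct an instrument set
#'
#' An instrument is a SNP carrying exposure-trait (`_X`) and outcome-trait
#' (`_Y`) effect estimates; the set is the atomic input of every MR
#' estimator.
#'
#' @param exposure component trait code.
#' @param outcome outcome trait code (normally `"YD"`).
#' @param instruments data.frame with columns
#'   SNP/CHR/POS/BETA_X/SE_X/P_X/BETA_Y/SE_Y/P_Y.
#' @return list of class `instrument_set`.
#' @export
instrument_set <- function(exposure, outcome, instruments) {
  need <- INSTRUMENT_COLS
  if (!all(need %in% names(instruments)))
    stopf("instrument table lacks columns: %s",
          paste(setdiff(need, names(instruments)), collapse = ", "))
  if (anyDuplicated(instruments$SNP))
    stopf("duplicated instrument snp id: %s",
          instruments$SNP[duplicated(instruments$SNP)][1])
  if (nrow(instruments) > 0 &&
      any(instruments$SE_X <= 0 | instruments$SE_Y <= 0))
    stopf("instrument standard errors must be positive")
  rownames(instruments) <- NULL
  structure(list(exposure = exposure, outcome = outcome,
                 instruments = instruments[, need]),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("instrument_set: %s -> %s, k = %d\n", x$exposure, x$outcome,
              nrow(x$instruments)))
  if (nrow(x$instruments)) print(x$instruments, digits = 4)
  invisible(x)
}

n_instruments <- function(s) nrow(s$instruments)

#' Back-derive a standard error from an effect size and p-value
#'
#' Inverts the two-sided normal test: `se = |beta| / qnorm(1 - p/2)`.
#' This is how published instrument tables that print only beta and p are
#' converted into the SEs all MR formulas need.
#'
#' @param beta effect size(s); must be non-zero when `p < 1`.
#' @param p two-sided p-value(s) in the open interval `(0, 1)`.
#' @return standard error(s), same length as the inputs.
#' @export
derive_se <- function(beta, p) {
  if (any(!is.finite(p) | p <= 0 | p >= 1))
    stopf("p must lie strictly inside (0, 1)")
  if (any(beta == 0 & p < 1))
    stopf("beta = 0 is incompatible with p < 1")
  # upper-tail form keeps full precision for very small p
  abs(beta) / qnorm(p / 2, lower.tail = FALSE)
}

#' LD between two SNPs as squared dosage correlation
#'
#' @param g a [genotype_matrix()].
#' @param snp_a,snp_b snp ids present in `g`.
#' @return squared Pearson correlation over jointly non-missing lines.
#' @export
ld_r2 <- function(g, snp_a, snp_b) {
  ia <- match(snp_a, g$snps$snp_id)
  ib <- match(snp_b, g$snps$snp_id)
  if (is.na(ia) || is.na(ib))
    stopf("snp not present: %s", if (is.na(ia)) snp_a else snp_b)
  x <- g$dosage[, ia]
  y <- g$dosage[, ib]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) stopf("fewer than 2 jointly non-missing lines")
  if (var(x[ok]) == 0 || var(y[ok]) == 0)
    stopf("LD undefined: zero dosage variance for %s",
          if (var(x[ok]) == 0) snp_a else snp_b)
  cor(x[ok], y[ok])^2
}

#' Select MR instruments from meta-GWAS summary statistics
#'
#' Implements the three instrumental-variable assumptions as filters:
#' (i) relevance -- exposure meta p strictly below `p_sig`;
#' (iii) exclusivity -- meta p strictly above `p_excl` in *every* other
#' component trait (a SNP absent from an exclusivity table cannot be
#' cleared and is excluded with a warning). Assumption (ii), no
#' confounder association, is not testable from summary data and is
#' addressed by design in simulation. Surviving candidates are greedily
#' LD-pruned: scanning in order of ascending exposure p (snp id breaking
#' ties), a SNP is accepted only if its r^2 with every already-accepted
#' SNP is at most `r2_max`, i.e. SNPs in LD are discarded based on the
#' larger p-value. Outcome effects are attached from `outcome_meta`.
#'
#' @param exposure_meta meta-statistic data.frame for the exposure trait.
#' @param other_traits_meta named list of meta data.frames for the other
#'   component traits.
#' @param outcome_meta meta data.frame for the outcome trait.
#' @param g a [genotype_matrix()] supplying dosages for the LD step.
#' @param p_sig genome-wide significance threshold (default 1e-6).
#' @param p_excl exclusivity threshold (default 0.05).
#' @param r2_max LD pruning threshold (default 0.01).
#' @param exposure,outcome trait codes for the resulting set.
#' @return an [instrument_set()]; empty (with a warning) when no SNP
#'   survives.
#' @export
select_instruments <- function(exposure_meta, other_traits_meta,
                               outcome_meta, g, p_sig = 1e-6,
                               p_excl = 0.05, r2_max = 0.01,
                               exposure = exposure_meta$TRAIT[1],
                               outcome = "YD") {
  cand <- exposure_meta[exposure_meta$P < p_sig, , drop = FALSE]
  n0 <- nrow(cand)
  for (tr in names(other_traits_meta)) {
    om <- other_traits_meta[[tr]]
    po <- om$P[match(cand$SNP, om$SNP)]
    missing_snp <- is.na(po)
    if (any(missing_snp))
      warnf("%d candidate(s) absent from the %s table were excluded",
            sum(missing_snp), tr)
    cand <- cand[!missing_snp & po > p_excl, , drop = FALSE]
  }
  n_excl <- nrow(cand)

  cand <- cand[order(cand$P, cand$SNP), , drop = FALSE]
  accepted <- integer(0)
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    for (j in accepted) {
      if (ld_r2(g, cand$SNP[i], cand$SNP[j]) > r2_max) { ok <- FALSE; break }
    }
    if (ok) accepted <- c(accepted, i)
  }
  cand <- cand[accepted, , drop = FALSE]

  oy <- outcome_meta[match(cand$SNP, outcome_meta$SNP), , drop = FALSE]
  no_outcome <- is.na(oy$SNP)
  if (any(no_outcome)) {
    warnf("%d instrument(s) absent from the outcome table were dropped",
          sum(no_outcome))
    cand <- cand[!no_outcome, , drop = FALSE]
    oy <- oy[!no_outcome, , drop = FALSE]
  }

  tab <- data.frame(SNP = cand$SNP, CHR = cand$CHR, POS = cand$POS,
                    BETA_X = cand$BETA, SE_X = cand$SE, P_X = cand$P,
                    BETA_Y = oy$BETA, SE_Y = oy$SE, P_Y = oy$P,
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$CHR, tab$POS), , drop = FALSE]
  if (nrow(tab) == 0L)
    warnf("no instrument survives selection for exposure %s", exposure)
  s <- instrument_set(exposure, outcome, tab)
  attr(s, "attrition") <- c(exposure_significant = n0,
                            exclusivity = n_excl, ld_pruned = nrow(tab))
  s
}
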