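#' Assign the superior genotype class at each locus
#'
#' For each SNP, lines are grouped by genotype class (0 = hom ref,
#' 1 = het, 2 = hom alt); the class with the highest mean of the relevant
#' trait among classes with at least one phenotyped line is the superior
#' genotype. Ties are broken deterministically towards the lower dosage
#' class. SNPs monomorphic in the phenotyped lines are skipped and listed
#' in the `skipped` attribute.
#'
#' @param g a [genotype_matrix()].
#' @param pheno named numeric vector (names = line ids) of the trait the
#'   loci were detected for.
#' @param snps snp ids to classify.
#' @return data.frame of class `superior_allele_map` with one row per SNP:
#'   superior class/label, per-class means and counts.
#' @export
assign_superior_alleles <- function(g, pheno, snps) {
  labels <- c(`0` = "hom_ref", `1` = "het", `2` = "hom_alt")
  lines <- intersect(g$line_ids, names(pheno)[!is.na(pheno)])
  if (length(lines) == 0L) stopf("no phenotyped line present in the panel")
  y <- pheno[lines]
  rows <- list()
  skipped <- character(0)
  for (snp in snps) {
    j <- match(snp, g$snps$snp_id)
    if (is.na(j)) stopf("snp not present: %s", snp)
    d <- g$dosage[lines, j]
    ok <- !is.na(d)
    classes <- sort(unique(d[ok]))
    if (length(classes) < 2L) {
      skipped <- c(skipped, snp)
      message(sprintf("assign_superior_alleles: %s monomorphic in phenotyped lines, skipped", snp))
      next
    }
    means <- counts <- setNames(rep(NA_real_, 3), c("0", "1", "2"))
    for (cl in classes) {
      sel <- ok & d == cl
      means[as.character(cl)] <- mean(y[sel])
      counts[as.character(cl)] <- sum(sel)
    }
    present <- !is.na(means)
    best_mean <- max(means[present])
    # lowest dosage class wins ties
    sup <- as.integer(names(means)[present][means[present] == best_mean][1])
    rows[[snp]] <- data.frame(
      SNP = snp, superior_class = sup,
      superior_label = labels[[as.character(sup)]],
      mean_0 = means[["0"]], mean_1 = means[["1"]], mean_2 = means[["2"]],
      n_0 = counts[["0"]], n_1 = counts[["1"]], n_2 = counts[["2"]],
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
  else data.frame()
  attr(out, "skipped") <- skipped
  class(out) <- c("superior_allele_map", class(out))
  out
}

#' Yield by superior-allele count
#'
#' Counts, per line, the loci at which the line carries the superior
#' genotype class, groups lines by that count, and reports group size and
#' mean yield. Groups with fewer than `min_lines` lines are omitted (but
#' reported in `omitted`); pairwise LSD comparisons are run across the
#' retained groups.
#'
#' @param g a [genotype_matrix()].
#' @param map a `superior_allele_map` from [assign_superior_alleles()].
#' @param yield_pheno named numeric vector of yield (g) per line.
#' @param min_lines smallest reportable group (default 3).
#' @return list of class `pyramid_summary`: `summary` (count, n_lines,
#'   mean_yield), `lsd` (pairwise table or NULL), `omitted`.
#' @export
pyramid_summary <- function(g, map, yield_pheno, min_lines = 3) {
  if (nrow(map) == 0L) stopf("empty superior-allele map")
  lines <- intersect(g$line_ids, names(yield_pheno)[!is.na(yield_pheno)])
  y <- yield_pheno[lines]
  jj <- match(map$SNP, g$snps$snp_id)
  D <- g$dosage[lines, jj, drop = FALSE]
  hits <- sweep(D, 2, map$superior_class, `==`)
  count <- rowSums(hits, na.rm = TRUE)

  groups <- split(y, count)
  tab <- data.frame(superior_allele_count = as.integer(names(groups)),
                    n_lines = vapply(groups, length, integer(1)),
                    mean_yield = vapply(groups, mean, numeric(1)))
  keep <- tab$n_lines >= min_lines
  omitted <- tab[!keep, , drop = FALSE]
  tab <- tab[keep, , drop = FALSE]
  tab <- tab[order(tab$superior_allele_count), , drop = FALSE]
  rownames(tab) <- rownames(omitted) <- NULL
  if (nrow(tab) == 0L) {
    warnf("no superior-allele-count group reaches %d lines", min_lines)
    return(structure(list(summary = tab, lsd = NULL, omitted = omitted),
                     class = "pyramid_summary"))
  }
  retained <- groups[as.character(tab$superior_allele_count)]
  # pairwise comparisons are reported when defined; degenerate toy data
  # (zero within-group variance) simply carries no LSD table
  lsd <- if (nrow(tab) >= 2L && all(tab$n_lines >= 2L))
    tryCatch(lsd_test(retained), error = function(e) NULL) else NULL
  structure(list(summary = tab, lsd = lsd, omitted = omitted),
            class = "pyramid_summary")
}

#' @export
print.pyramid_summary <- function(x, ...) {
  print(x$summary, digits = 4)
  if (nrow(x$omitted))
    cat(sprintf("(%d group(s) with < 3 lines omitted)\n", nrow(x$omitted)))
  invisible(x)
}

#' Least-significant-difference multiple comparisons
#'
#' One-way ANOVA pooled error mean square, then for each pair of groups
#' `t = |mean_a - mean_b| / sqrt(MSE (1/n_a + 1/n_b))` on `N - k` degrees
#' of freedom.
#'
#' @param groups named list of numeric vectors, each of length >= 2.
#' @param alpha significance level for the `significant` flag.
#' @return data.frame with one row per pair: difference, t, df, p,
#'   significance flag; the pooled `mse` and error `df` are attached as
#'   attributes.
#' @export
lsd_test <- function(groups, alpha = 0.05) {
  if (length(groups) < 2L) stopf("lsd_test needs at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2L))
    stopf("every group needs n >= 2")
  if (is.null(names(groups))) names(groups) <- seq_along(groups)
  n <- vapply(groups, length, integer(1))
  mu <- vapply(groups, mean, numeric(1))
  N <- sum(n)
  k <- length(groups)
  sse <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  df <- N - k
  mse <- sse / df
  if (mse == 0) stopf("degenerate data: zero pooled variance")
  pairs <- utils::combn(k, 2)
  out <- data.frame(
    group_a = names(groups)[pairs[1, ]],
    group_b = names(groups)[pairs[2, ]],
    diff = mu[pairs[1, ]] - mu[pairs[2, ]],
    stringsAsFactors = FALSE)
  out$t <- abs(out$diff) / sqrt(mse * (1 / n[pairs[1, ]] + 1 / n[pairs[2, ]]))
  out$df <- df
  out$p <- 2 * pt(-out$t, df)
  out$significant <- out$p < alpha
  rownames(out) <- NULL
  attr(out, "mse") <- mse
  attr(out, "df") <- df
  out
}
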