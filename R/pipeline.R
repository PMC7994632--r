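#' Pipeline configuration
#'
#' Bundles the [study_config()] with every downstream threshold: per-
#' population QC (the smaller resequenced panel is held to MAF > 5%, the
#' large public panel to MAF > 1%), genome-wide meta significance
#' (P < 1e-6), instrument exclusivity (P > 0.05) and LD pruning
#' (r^2 <= 0.01), MR bootstrap settings, and the smallest reportable
#' pyramiding group (3 lines). The default demo study is deliberately
#' desk-scale: one population of 500 lines, two environments, 2000 SNPs.
#'
#' @param study a [study_config()].
#' @param maf_min named numeric vector of per-population MAF thresholds;
#'   populations not named fall back to `default_maf_min`.
#' @param default_maf_min fallback MAF threshold (default 0.05).
#' @param missing_max missing-rate threshold (default 0.20).
#' @param meta_alpha genome-wide significance for the meta stage.
#' @param p_excl,r2_max instrument-selection thresholds.
#' @param n_boot,mr_seed weighted-median bootstrap settings.
#' @param min_lines smallest pyramiding group (default 3).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(study = study_config(
                              populations = data.frame(population = "P1",
                                                       n_lines = 500),
                              n_snps = 2000),
                            maf_min = c(P1 = 0.05),
                            default_maf_min = 0.05,
                            missing_max = 0.20,
                            meta_alpha = 1e-6,
                            p_excl = 0.05,
                            r2_max = 0.01,
                            n_boot = 2000,
                            mr_seed = 1,
                            min_lines = 3) {
  stopifnot(inherits(study, "study_config"),
            meta_alpha > 0, meta_alpha < 1,
            p_excl >= 0, p_excl <= 1, r2_max >= 0, r2_max <= 1,
            min_lines >= 1)
  structure(list(study = study, maf_min = maf_min,
                 default_maf_min = default_maf_min,
                 missing_max = missing_max, meta_alpha = meta_alpha,
                 p_excl = p_excl, r2_max = r2_max, n_boot = n_boot,
                 mr_seed = mr_seed, min_lines = min_lines),
            class = "pipeline_config")
}

#' Run the full simulation-to-MR pipeline
#'
#' Executes, in order: study simulation, per-dataset x per-trait
#' mixed-model GWAS, per-trait meta-analysis, instrument selection for
#' each component exposure (the other two components acting as
#' exclusivity screens), the three MR estimators (with a sign-split
#' analysis whenever an instrument set carries ratios of both signs),
#' superior-allele pyramiding over the detected direct (yield) and
#' indirect (component) loci, and optional candidate-gene annotation.
#' Every stage writes a TSV under `workdir` and appends its parameters
#' and SNP-count attrition to `pipeline_log.txt`. The run is fully
#' deterministic given the config seeds; the returned manifest lists
#' every artifact with its md5 checksum.
#'
#' @param config a [pipeline_config()].
#' @param workdir output directory (created if needed).
#' @param genes optional gene-model data.frame for the annotation stage.
#' @return data.frame manifest (file, md5), invisibly; the MR result
#'   table is attached as attribute `mr_results`.
#' @export
run_pipeline <- function(config, workdir, genes = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(workdir, "pipeline_log.txt")
  unlink(logfile)
  logline <- function(fmt, ...) cat(sprintf(paste0(fmt, "\n"), ...),
                                    file = logfile, append = TRUE)
  written <- character(0)
  emit <- function(path) written <<- c(written, path)

  logline("stage simulate: seed=%d", config$study$seed)
  study <- simulate_study(config$study)
  for (p in write_study(study, workdir)) emit(p)
  datasets <- names(study$genotypes)
  logline("  datasets: %s", paste(datasets, collapse = ", "))

  # per-dataset QC + GWAS; GRM eigendecomposition shared across traits
  stats <- list()
  for (ds in datasets) {
    pop <- sub("_[^_]+$", "", ds)
    maf <- if (pop %in% names(config$maf_min)) config$maf_min[[pop]]
    else config$default_maf_min
    g0 <- study$genotypes[[ds]]
    g <- qc_filter(g0, maf, config$missing_max)
    logline("stage gwas %s: maf_min=%g missing_max=%g snps %d -> %d",
            ds, maf, config$missing_max, nrow(g0$snps), nrow(g$snps))
    eig <- grm_eigen(compute_grm(g))
    for (tr in TRAITS) {
      y <- phenotype_vector(study, ds, tr)
      y <- y[match(g$line_ids, names(y))]
      vc <- fit_null_lmm(as.vector(y), eig)
      st <- mlma_scan(g, as.vector(y), vc, eig, trait = tr, dataset_id = ds)
      logline("  %s: h2=%.3f, %d SNPs tested", tr, vc$h2, nrow(st))
      path <- file.path(workdir, sprintf("gwas_%s_%s.tsv", ds, tr))
      write_summary_stats(st, path)
      emit(path)
      stats[[paste(ds, tr)]] <- st
    }
  }

  # meta per trait
  meta <- list()
  for (tr in TRAITS) {
    per_ds <- stats[paste(datasets, tr)]
    res <- run_meta_gwas(per_ds, trait = tr, alpha = config$meta_alpha)
    meta[[tr]] <- res$meta
    logline("stage meta %s: alpha=%g, %d SNPs, %d significant", tr,
            config$meta_alpha, nrow(res$meta), nrow(res$significant))
    path <- file.path(workdir, sprintf("meta_%s.tsv", tr))
    write_meta_stats(res$meta, path)
    emit(path)
    path <- file.path(workdir, sprintf("meta_%s_significant.tsv", tr))
    write_meta_stats(res$significant, path)
    emit(path)
  }

  # instruments + MR per component exposure
  g_ld <- study$genotypes[[datasets[1]]]
  mr_rows <- list()
  sets <- list()
  for (tr in COMPONENT_TRAITS) {
    others <- meta[setdiff(COMPONENT_TRAITS, tr)]
    s <- select_instruments(meta[[tr]], others, meta$YD, g_ld,
                            p_sig = config$meta_alpha,
                            p_excl = config$p_excl,
                            r2_max = config$r2_max,
                            exposure = tr)
    sets[[tr]] <- s
    att <- attr(s, "attrition")
    logline("stage instruments %s: significant=%d exclusive=%d pruned=%d",
            tr, att[1], att[2], att[3])
    path <- file.path(workdir, sprintf("instruments_%s.tsv", tr))
    write_instruments(s, path)
    emit(path)
    if (n_instruments(s) == 0L) {
      logline("  no instruments: MR skipped for %s", tr)
      next
    }
    mr_rows[[tr]] <- mr_all(s, config$n_boot, config$mr_seed)
    ratio <- s$instruments$BETA_Y / s$instruments$BETA_X
    if (any(ratio >= 0) && any(ratio < 0)) {
      halves <- split_by_ratio_sign(s)
      for (side in names(halves)) {
        if (n_instruments(halves[[side]]) == 0L) next
        mr_rows[[paste(tr, side)]] <-
          mr_all(halves[[side]], config$n_boot, config$mr_seed,
                 label = sprintf("%s (%s)", tr, side))
      }
    }
  }
  mr_results <- if (length(mr_rows)) do.call(rbind, c(mr_rows, make.row.names = FALSE))
  else data.frame()
  path <- file.path(workdir, "mr_results.tsv")
  write.table(mr_results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  emit(path)
  logline("stage mr: %d result rows", nrow(mr_results))

  # pyramiding on pooled lines: line-level mean yield across datasets
  pool <- pool_panel(study)
  direct_loci <- prune_significant(meta$YD, g_ld, config$meta_alpha,
                                   config$r2_max)
  indirect_loci <- lapply(sets, function(s) s$instruments$SNP)
  pyr_sets <- list(direct = list(snps = direct_loci, trait = "YD"),
                   indirect = list(
                     snps = indirect_loci,
                     trait = NULL))  # defining trait varies per locus
  for (kind in names(pyr_sets)) {
    spec <- pyr_sets[[kind]]
    maps <- list()
    if (kind == "direct") {
      if (length(spec$snps))
        maps[["YD"]] <- assign_superior_alleles(pool$g, pool$pheno$YD,
                                                spec$snps)
    } else {
      for (tr in COMPONENT_TRAITS) {
        if (length(spec$snps[[tr]]))
          maps[[tr]] <- assign_superior_alleles(pool$g, pool$pheno[[tr]],
                                                spec$snps[[tr]])
      }
    }
    maps <- maps[vapply(maps, nrow, integer(1)) > 0]
    if (!length(maps)) {
      logline("stage pyramid %s: no loci", kind)
      next
    }
    map <- do.call(rbind, c(maps, make.row.names = FALSE))
    class(map) <- c("superior_allele_map", "data.frame")
    ps <- pyramid_summary(pool$g, map, pool$pheno$YD, config$min_lines)
    logline("stage pyramid %s: %d loci, %d retained groups, %d omitted",
            kind, nrow(map), nrow(ps$summary), nrow(ps$omitted))
    path <- file.path(workdir, sprintf("pyramid_%s.tsv", kind))
    write.table(ps$summary, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    emit(path)
  }

  if (!is.null(genes)) {
    sig_all <- do.call(rbind, lapply(meta, function(mtab)
      mtab[mtab$P < config$meta_alpha, c("SNP", "CHR", "POS", "TRAIT")]))
    ann <- annotate_snps(sig_all, genes)
    path <- file.path(workdir, "candidate_genes.tsv")
    write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
    emit(path)
    logline("stage annotate: %d SNPs annotated", nrow(ann))
  }

  emit(logfile)
  manifest <- data.frame(file = basename(written),
                         md5 = unname(tools::md5sum(written)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), ]
  rownames(manifest) <- NULL
  path <- file.path(workdir, "manifest.tsv")
  write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  attr(manifest, "mr_results") <- mr_results
  invisible(manifest)
}

# rbind the population panels (shared snp set) and average each line's
# phenotype over its datasets
pool_panel <- function(study) {
  datasets <- names(study$genotypes)
  pops <- unique(sub("_[^_]+$", "", datasets))
  gs <- lapply(pops, function(p) {
    study$genotypes[[datasets[startsWith(datasets, paste0(p, "_"))][1]]]
  })
  d <- do.call(rbind, lapply(gs, `[[`, "dosage"))
  g <- genotype_matrix(d, gs[[1]]$snps, unlist(lapply(gs, `[[`, "line_ids")))
  ph <- study$phenotypes
  pheno <- lapply(setNames(TRAITS, TRAITS), function(tr) {
    sub <- ph[ph$trait == tr & !is.na(ph$value), ]
    tapply(sub$value, sub$line_id, mean)
  })
  list(g = g, pheno = pheno)
}

# significant meta SNPs, greedily LD-pruned nearest-first by p
prune_significant <- function(meta_tab, g, alpha, r2_max) {
  sig <- meta_tab[meta_tab$P < alpha, , drop = FALSE]
  sig <- sig[sig$SNP %in% g$snps$snp_id, , drop = FALSE]
  sig <- sig[order(sig$P, sig$SNP), , drop = FALSE]
  accepted <- character(0)
  for (i in seq_len(nrow(sig))) {
    ok <- all(vapply(accepted, function(a)
      ld_r2(g, sig$SNP[i], a) <= r2_max, logical(1)))
    if (ok) accepted <- c(accepted, sig$SNP[i])
  }
  accepted
}

#' Published instrument tables
#'
#' The per-SNP instrument tables reported by a published meta-GWAS of two
#' hybrid rice panels (575 + 1495 F1 lines, two environments each):
#' for each instrument the exposure (component-trait) and outcome (yield)
#' effect size and p-value. Shipped as plain TSVs under `extdata`.
#'
#' @return named list (`GPP`, `KGW`, `TP`) of raw data.frames with columns
#'   SNP/CHR/POS/BETA_X/P_X/BETA_Y/P_Y.
#' @export
published_instrument_tables <- function() {
  read1 <- function(tr) {
    f <- system.file("extdata",
                     sprintf("published_instruments_%s.tsv", tolower(tr)),
                     package = "ricemr", mustWork = TRUE)
    read.delim(f, sep = "\t", stringsAsFactors = FALSE)
  }
  lapply(setNames(COMPONENT_TRAITS, COMPONENT_TRAITS), read1)
}

#' Published instrument sets with back-derived standard errors
#'
#' Converts [published_instrument_tables()] into [instrument_set()]s: the
#' tables print only beta and p, so each SE is reconstructed with
#' [derive_se()] under the two-sided normal reference.
#'
#' @return named list (`GPP`, `KGW`, `TP`) of instrument sets with
#'   exposure = the component trait and outcome = `YD`.
#' @export
published_instruments <- function() {
  tabs <- published_instrument_tables()
  out <- lapply(names(tabs), function(tr) {
    tab <- tabs[[tr]]
    tab$SE_X <- derive_se(tab$BETA_X, tab$P_X)
    tab$SE_Y <- derive_se(tab$BETA_Y, tab$P_Y)
    instrument_set(tr, "YD", tab[, INSTRUMENT_COLS])
  })
  setNames(out, names(tabs))
}

#' MR report on the published instrument tables
#'
#' Runs IVW, weighted median and MR-Egger on the published GPP, KGW and
#' TP instrument sets; the KGW set, whose Wald ratios point in both
#' directions, is additionally split by ratio sign and each subgroup
#' analysed separately. Output mirrors the usual MR reporting layout
#' (method, Beta, 95% CI, P, Egger intercept).
#'
#' @param n_boot,seed bootstrap settings for the weighted-median SE (the
#'   point estimates are deterministic).
#' @return data.frame with one row per trait x method.
#' @export
published_mr_report <- function(n_boot = 10000, seed = 1) {
  sets <- published_instruments()
  rows <- list(mr_all(sets$GPP, n_boot, seed))
  halves <- split_by_ratio_sign(sets$KGW)
  rows <- c(rows,
            list(mr_all(halves$positive, n_boot, seed, "KGW (positive)"),
                 mr_all(halves$negative, n_boot, seed, "KGW (negative)"),
                 mr_all(sets$TP, n_boot, seed)))
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  het <- lapply(list(GPP = sets$GPP, TP = sets$TP), mr_heterogeneity)
  attr(out, "heterogeneity") <- het
  out
}
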