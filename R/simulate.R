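#' Simulate an LD-structured biallelic genotype panel
#'
#' Each line is formed from two independent haplotypes drawn from a
#' first-order copying process: along a chromosome, the allele at SNP j
#' copies the allele at SNP j-1 with probability `ld_rho`, otherwise it is
#' a fresh Bernoulli draw at that SNP's own frequency. The process restarts
#' at every chromosome boundary, so LD decays geometrically with marker
#' distance and is zero across chromosomes. Per-SNP ALT frequencies are
#' drawn uniformly in `maf_range`.
#'
#' @param n_lines number of lines (>= 2).
#' @param n_snps number of SNPs (>= 1), split into `n_chrom` contiguous
#'   blocks at 10-kb spacing.
#' @param maf_range length-2 numeric in `(0, 0.5]`, `low < high`.
#' @param ld_rho haplotype copying probability in `[0, 1)`.
#' @param seed integer seed; the same seed yields a bit-identical panel.
#' @param n_chrom number of chromosomes to spread SNPs over (default 12,
#'   the rice karyotype).
#' @param line_prefix prefix for auto-generated line ids.
#' @return a [genotype_matrix()] with attributes `allele_freq` (the drawn
#'   per-SNP ALT frequencies) and `chrom_start` (indices where chromosomes
#'   begin).
#' @export
simulate_genotypes <- function(n_lines, n_snps, maf_range = c(0.05, 0.5),
                               ld_rho = 0, seed = 1, n_chrom = 12,
                               line_prefix = "L") {
  if (n_lines < 2) stopf("n_lines must be >= 2")
  if (n_snps < 1) stopf("n_snps must be >= 1")
  if (length(maf_range) != 2 || maf_range[1] >= maf_range[2])
    stopf("degenerate maf_range: low (%g) must be < high (%g)",
          maf_range[1], maf_range[2])
  if (maf_range[1] <= 0 || maf_range[2] > 0.5)
    stopf("maf_range must lie in (0, 0.5]")
  if (ld_rho < 0 || ld_rho >= 1) stopf("ld_rho must be in [0, 1)")
  set.seed(seed)

  n_chrom <- min(n_chrom, n_snps)
  sizes <- diff(floor(seq(0, n_snps, length.out = n_chrom + 1)))
  chrom <- rep(seq_len(n_chrom), sizes)
  pos <- unlist(lapply(sizes, function(s) 10000L * seq_len(s)), use.names = FALSE)
  new_chrom <- c(TRUE, diff(chrom) != 0)

  f <- runif(n_snps, maf_range[1], maf_range[2])
  nh <- 2L * n_lines
  H <- matrix(0L, nh, n_snps)
  for (j in seq_len(n_snps)) {
    fresh <- rbinom(nh, 1L, f[j])
    if (j == 1L || new_chrom[j] || ld_rho == 0) {
      H[, j] <- fresh
    } else {
      copy <- rbinom(nh, 1L, ld_rho)
      H[, j] <- ifelse(copy == 1L, H[, j - 1L], fresh)
    }
  }
  dosage <- H[seq(1L, nh, by = 2L), , drop = FALSE] +
    H[seq(2L, nh, by = 2L), , drop = FALSE]

  g <- genotype_matrix(
    dosage,
    data.frame(chrom = chrom, pos = pos, allele_ref = "A", allele_alt = "G",
               stringsAsFactors = FALSE),
    sprintf("%s%04d", line_prefix, seq_len(n_lines)))
  attr(g, "allele_freq") <- setNames(f, g$snps$snp_id)
  attr(g, "chrom_start") <- which(new_chrom)
  g
}

#' Configuration of a simulated hybrid study
#'
#' Bundles panel layout and causal architecture for [simulate_study()].
#' Defaults emulate the study design the package targets: hybrid rice
#' panels phenotyped in two environments, three component traits with a
#' handful of moderate-effect causal SNPs on a polygenic background, and
#' yield generated as a weighted combination of the components plus a few
#' direct-effect loci. The default yield weights (0.1 g per grain, 1.0 g
#' per g KGW, 1.9 g per tiller) follow the linearised grain-number x
#' grain-weight x tiller-number product rule at typical trait means.
#'
#' @param populations data.frame with columns `population` and `n_lines`.
#' @param environments character vector of environment codes; every
#'   population is phenotyped in every environment and `dataset_id` is
#'   `"<population>_<environment>"`.
#' @param n_snps,maf_range,ld_rho,n_chrom passed to [simulate_genotypes()].
#' @param n_causal named integer vector: causal SNPs per component trait.
#' @param effect_size named numeric vector: absolute per-dosage effect of
#'   each causal SNP in trait units (sign is randomised per SNP).
#' @param h2 named numeric vector of narrow-sense heritabilities in `[0,1]`
#'   for the component traits.
#' @param yield_weights named numeric vector `c(GPP=, KGW=, TP=)`: grams of
#'   yield per unit of each component.
#' @param n_direct,direct_effect number and absolute effect (g) of loci
#'   acting on yield directly rather than through a component.
#' @param yield_noise_sd residual SD (g) of the yield channel.
#' @param polygenic_prop fraction of each component's genetic variance due
#'   to the polygenic background (small effects at `n_polygenic` SNPs).
#' @param n_polygenic number of background SNPs per trait.
#' @param intercepts named trait means at zero genetic value.
#' @param env_shifts named list: per environment, a named numeric vector of
#'   additive trait offsets.
#' @param residual_sd optional named numeric vector of per-trait residual
#'   SDs. When supplied it is used directly and the `h2`-based noise
#'   tuning is bypassed -- the way to express a global-null study whose
#'   traits are pure noise.
#' @param exclusive if `TRUE` (default), causal SNP sets of different
#'   component traits and the direct-yield set are disjoint and spaced at
#'   least `min_causal_gap` markers apart, so valid MR instruments exist.
#' @param min_causal_gap minimum marker-index gap between planted loci.
#' @param seed integer master seed.
#' @return a list of class `study_config`.
#' @export
study_config <- function(populations = data.frame(population = "P1",
                                                  n_lines = 1000),
                         environments = c("E1", "E2"),
                         n_snps = 5000,
                         maf_range = c(0.05, 0.5),
                         ld_rho = 0.25,
                         n_chrom = 12,
                         n_causal = c(GPP = 8, KGW = 8, TP = 8),
                         effect_size = c(GPP = 4, KGW = 0.6, TP = 0.5),
                         h2 = c(GPP = 0.5, KGW = 0.5, TP = 0.5),
                         yield_weights = c(GPP = 0.1, KGW = 1.0, TP = 1.9),
                         n_direct = 3,
                         direct_effect = 1.5,
                         yield_noise_sd = 2,
                         polygenic_prop = 0.3,
                         n_polygenic = 200,
                         intercepts = c(GPP = 150, KGW = 25, TP = 9),
                         env_shifts = list(E2 = c(GPP = 5, KGW = 0.5,
                                                  TP = -0.5)),
                         residual_sd = NULL,
                         exclusive = TRUE,
                         min_causal_gap = 25,
                         seed = 42) {
  if (any(h2 < 0 | h2 > 1))
    stopf("h2 must lie in [0, 1]; got %s",
          paste(format(h2), collapse = ", "))
  if (!all(COMPONENT_TRAITS %in% names(h2)))
    stopf("h2 must be named for all of %s",
          paste(COMPONENT_TRAITS, collapse = ", "))
  if (!all(is.finite(yield_weights)))
    stopf("yield_weights must be finite")
  structure(list(populations = populations, environments = environments,
                 n_snps = n_snps, maf_range = maf_range, ld_rho = ld_rho,
                 n_chrom = n_chrom, n_causal = n_causal,
                 effect_size = effect_size, h2 = h2,
                 yield_weights = yield_weights, n_direct = n_direct,
                 direct_effect = direct_effect,
                 yield_noise_sd = yield_noise_sd,
                 polygenic_prop = polygenic_prop,
                 n_polygenic = n_polygenic, intercepts = intercepts,
                 env_shifts = env_shifts, residual_sd = residual_sd,
                 exclusive = exclusive,
                 min_causal_gap = min_causal_gap, seed = seed),
            class = "study_config")
}

# sample planted loci on a coarse grid so any two are >= gap markers
# apart; on panels too small for the requested gap the grid is tightened
# to the widest feasible spacing (disjointness is always preserved)
sample_spaced_loci <- function(n_snps, n_needed, gap) {
  if (n_needed == 0L) return(integer(0))
  if (n_needed > n_snps)
    stopf("cannot place %d loci in %d SNPs", n_needed, n_snps)
  gap <- max(1L, min(gap, n_snps %/% n_needed))
  grid <- seq(1L, n_snps, by = gap)
  sort(sample(grid, n_needed))
}

#' Simulate a complete multi-population, multi-environment study
#'
#' For every population one genotype panel is drawn (shared by all of its
#' environments). Component traits are `intercept + genetic value +
#' environment shift + noise`, where the genetic value is the planted
#' causal effects plus a rescaled polygenic background and the noise SD is
#' tuned so the in-sample genetic variance fraction equals the requested
#' heritability. Yield is the weighted sum of the realised component
#' phenotypes plus direct-effect loci and independent noise, so each
#' component's true causal effect on yield is exactly its weight.
#'
#' @param config a [study_config()].
#' @return a list of class `simulated_study`: `genotypes` (named by
#'   dataset_id), `phenotypes` (long data.frame), `truth` (the planted
#'   causal architecture, class `truth_record`), and `genetic_values`
#'   (per population, each line's realised genetic value per component
#'   trait -- the reference for heritability checks).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  set.seed(config$seed)
  pops <- config$populations
  pop_seeds <- sample.int(2^31 - 1, nrow(pops))

  n_comp_causal <- sum(config$n_causal[COMPONENT_TRAITS])
  loci <- if (config$exclusive) {
    sample_spaced_loci(config$n_snps, n_comp_causal + config$n_direct,
                       config$min_causal_gap)
  } else {
    sort(sample.int(config$n_snps, n_comp_causal + config$n_direct))
  }
  loci <- sample(loci)  # random assignment to traits
  idx <- 0L
  component_effects <- list()
  for (tr in COMPONENT_TRAITS) {
    k <- config$n_causal[[tr]]
    pick <- if (k > 0) loci[idx + seq_len(k)] else integer(0)
    idx <- idx + k
    component_effects[[tr]] <- data.frame(
      snp_index = pick,
      effect = if (k > 0) sample(c(-1, 1), k, replace = TRUE) *
        config$effect_size[[tr]] else numeric(0))
  }
  direct_idx <- if (config$n_direct > 0) loci[idx + seq_len(config$n_direct)] else integer(0)
  direct_effects <- data.frame(
    snp_index = direct_idx,
    effect = if (config$n_direct > 0)
      sample(c(-1, 1), config$n_direct, replace = TRUE) * config$direct_effect
    else numeric(0))

  all_causal <- c(unlist(lapply(component_effects, `[[`, "snp_index")),
                  direct_idx)
  poly_idx <- lapply(COMPONENT_TRAITS, function(tr) {
    pool <- setdiff(seq_len(config$n_snps), all_causal)
    sample(pool, min(config$n_polygenic, length(pool)))
  })
  names(poly_idx) <- COMPONENT_TRAITS
  poly_coef <- lapply(poly_idx, function(ix) rnorm(length(ix)))

  genotypes <- list()
  pheno <- list()
  genetic_values <- list()
  snp_ids <- NULL
  for (pi in seq_len(nrow(pops))) {
    pop <- pops$population[pi]
    g <- simulate_genotypes(pops$n_lines[pi], config$n_snps,
                            config$maf_range, config$ld_rho,
                            seed = pop_seeds[pi], n_chrom = config$n_chrom,
                            line_prefix = paste0(pop, "_L"))
    snp_ids <- g$snps$snp_id
    X <- g$dosage
    n <- nrow(X)

    gval <- list()
    noise_sd <- list()
    for (tr in COMPONENT_TRAITS) {
      ce <- component_effects[[tr]]
      causal <- if (nrow(ce)) as.vector(X[, ce$snp_index, drop = FALSE] %*%
                                          ce$effect) else numeric(n)
      poly <- as.vector(X[, poly_idx[[tr]], drop = FALSE] %*% poly_coef[[tr]])
      v_c <- var(causal)
      v_p <- var(poly)
      if (v_c > 0 && v_p > 0) {
        target <- config$polygenic_prop / (1 - config$polygenic_prop) * v_c
        poly <- poly * sqrt(target / v_p)
      } else if (v_p > 0) {
        poly <- poly / sqrt(v_p)  # unit-variance background when no causal
      }
      gv <- causal + poly
      v_g <- var(gv)
      h2 <- config$h2[[tr]]
      if (!is.null(config$residual_sd)) {
        sd_e <- config$residual_sd[[tr]]
      } else if (v_g == 0) {
        sd_e <- 0
      } else if (h2 == 0) {
        stopf("h2(%s) = 0 is incompatible with non-zero genetic effects", tr)
      } else {
        sd_e <- sqrt(v_g * (1 - h2) / h2)
      }
      gval[[tr]] <- gv
      noise_sd[[tr]] <- sd_e
    }
    genetic_values[[pop]] <- gval
    direct <- if (nrow(direct_effects))
      as.vector(X[, direct_effects$snp_index, drop = FALSE] %*%
                  direct_effects$effect) else numeric(n)

    for (env in config$environments) {
      ds <- paste(pop, env, sep = "_")
      genotypes[[ds]] <- g
      shifts <- config$env_shifts[[env]]
      comp <- list()
      for (tr in COMPONENT_TRAITS) {
        sh <- if (!is.null(shifts) && tr %in% names(shifts)) shifts[[tr]] else 0
        comp[[tr]] <- config$intercepts[[tr]] + gval[[tr]] + sh +
          rnorm(n, 0, noise_sd[[tr]])
      }
      yd_sh <- if (!is.null(shifts) && "YD" %in% names(shifts)) shifts[["YD"]] else 0
      yd <- config$yield_weights[["GPP"]] * comp$GPP +
        config$yield_weights[["KGW"]] * comp$KGW +
        config$yield_weights[["TP"]] * comp$TP +
        direct + yd_sh + rnorm(n, 0, config$yield_noise_sd)
      for (tr in TRAITS) {
        vals <- if (tr == "YD") yd else comp[[tr]]
        pheno[[paste(ds, tr)]] <- data.frame(
          line_id = g$line_ids, dataset_id = ds, trait = tr, value = vals,
          stringsAsFactors = FALSE)
      }
    }
  }

  add_id <- function(df) { df$snp_id <- snp_ids[df$snp_index]; df }
  truth <- structure(list(
    component_effects = lapply(component_effects, add_id),
    yield_weights = config$yield_weights,
    direct_yield_effects = add_id(direct_effects),
    heritability = config$h2,
    env_shifts = config$env_shifts,
    polygenic = list(indices = poly_idx, prop = config$polygenic_prop),
    seed = config$seed), class = "truth_record")

  structure(list(genotypes = genotypes,
                 phenotypes = do.call(rbind, c(pheno, make.row.names = FALSE)),
                 truth = truth,
                 genetic_values = genetic_values),
            class = "simulated_study")
}

#' Extract one trait's phenotype vector for one dataset
#'
#' @param study a `simulated_study` or any object with a long `phenotypes`
#'   data.frame.
#' @param dataset_id,trait selectors.
#' @return named numeric vector (names = line ids), missing values kept.
#' @export
phenotype_vector <- function(study, dataset_id, trait) {
  ph <- if (is.data.frame(study)) study else study$phenotypes
  sel <- ph$dataset_id == dataset_id & ph$trait == trait
  setNames(ph$value[sel], ph$line_id[sel])
}

#' Write a simulated study to disk
#'
#' Emits one dosage TSV per population, the phenotype TSV, and the planted
#' truth as JSON.
#'
#' @param study a `simulated_study`.
#' @param dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  seen <- character(0)
  for (ds in names(study$genotypes)) {
    pop <- sub("_[^_]+$", "", ds)
    if (pop %in% seen) next
    seen <- c(seen, pop)
    p <- file.path(dir, sprintf("genotypes_%s.tsv", pop))
    write_genotypes(study$genotypes[[ds]], p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "phenotypes.tsv")
  write_phenotypes(study$phenotypes, p)
  paths <- c(paths, p)
  p <- file.path(dir, "truth.json")
  tr <- unclass(study$truth)
  tr$yield_weights <- as.list(tr$yield_weights)     # keep trait names
  tr$heritability <- as.list(tr$heritability)
  jsonlite::write_json(tr, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}
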