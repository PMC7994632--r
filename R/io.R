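#' Construct a genotype matrix
#'
#' Container for a panel of lines typed at biallelic SNPs. Dosage counts
#' copies of the ALT allele, so values are 0, 1, 2 or `NA` (missing).
#'
#' @param dosage numeric matrix, rows = lines, columns = SNPs, values in
#'   \{0, 1, 2, NA\}.
#' @param snps data.frame with columns `snp_id`, `chrom` (integer 1-12),
#'   `pos` (1-based), `allele_ref`, `allele_alt`. If `snp_id` is missing it
#'   is auto-generated as `chr{chrom, zero-padded to 2}_{pos}`.
#' @param line_ids character vector of line identifiers.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosage`, `snps` and `line_ids`.
#' @export
genotype_matrix <- function(dosage, snps, line_ids) {
  dosage <- as.matrix(dosage)
  if (is.null(snps$snp_id)) {
    snps$snp_id <- sprintf("chr%02d_%d", snps$chrom, snps$pos)
  }
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  if (nrow(snps) != ncol(dosage))
    stopf("dosage has %d columns but %d SNP records supplied",
          ncol(dosage), nrow(snps))
  if (length(line_ids) != nrow(dosage))
    stopf("dosage has %d rows but %d line ids supplied",
          nrow(dosage), length(line_ids))
  if (anyDuplicated(snps$snp_id))
    stopf("duplicated snp_id: %s", snps$snp_id[duplicated(snps$snp_id)][1])
  if (anyDuplicated(paste(snps$chrom, snps$pos)))
    stopf("duplicated (chrom, pos) pair in SNP table")
  bad <- !(dosage %in% c(0, 1, 2) | is.na(dosage))
  if (any(bad))
    stopf("%d dosage values outside {0, 1, 2, NA}", sum(bad))
  dimnames(dosage) <- list(line_ids, snps$snp_id)
  structure(list(dosage = dosage, snps = snps, line_ids = line_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d lines x %d SNPs (%.1f%% missing)\n",
              length(x$line_ids), nrow(x$snps),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Per-SNP minor allele frequency
#'
#' ALT-allele frequency is computed from non-missing dosages; the MAF is
#' `min(f, 1 - f)` and therefore lies in `[0, 0.5]`.
#'
#' @param g a [genotype_matrix()].
#' @return named numeric vector of MAFs.
#' @export
snp_maf <- function(g) {
  f <- colMeans(g$dosage, na.rm = TRUE) / 2
  pmin(f, 1 - f)
}

#' Per-SNP missing fraction
#' @param g a [genotype_matrix()].
#' @return named numeric vector in `[0, 1]`.
#' @export
snp_missing_rate <- function(g) colMeans(is.na(g$dosage))

#' Read genotypes from VCF or dosage TSV
#'
#' The dosage TSV layout is one header row (`line_id` followed by snp ids),
#' one row per line, `.` for missing. SNP chromosome/position are recovered
#' from ids of the form `chrNN_POS`; REF/ALT alleles default to A/G unless a
#' sidecar SNP table is supplied. VCF input must contain biallelic SNPs
#' only; any multiallelic or non-SNP record is rejected by name.
#'
#' @param path input file.
#' @param format `"tsv"` (dosage TSV) or `"vcf"`.
#' @param snp_file optional TSV with columns SNP/CHR/POS/REF/ALT overriding
#'   the metadata recovered from ids (dosage TSV only).
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf"), snp_file = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "vcf") return(read_genotypes_vcf(path))

  hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 2L || hdr[1] != "line_id")
    stopf("malformed dosage TSV header at line 1 of %s: first column must be 'line_id'",
          path)
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    na.strings = ".", colClasses = c("character"))
  snp_ids <- hdr[-1]
  dosage <- matrix(NA_real_, nrow(tab), length(snp_ids))
  for (j in seq_along(snp_ids)) dosage[, j] <- as.numeric(tab[[j + 1L]])
  if (!is.null(snp_file)) {
    st <- read.delim(snp_file, sep = "\t", stringsAsFactors = FALSE)
    snps <- data.frame(snp_id = st$SNP, chrom = as.integer(st$CHR),
                       pos = as.integer(st$POS), allele_ref = st$REF,
                       allele_alt = st$ALT, stringsAsFactors = FALSE)
    snps <- snps[match(snp_ids, snps$snp_id), ]
  } else {
    m <- regmatches(snp_ids, regexec("^chr([0-9]+)_([0-9]+)$", snp_ids))
    ok <- lengths(m) == 3L
    if (!all(ok))
      stopf("snp id '%s' does not follow the chrNN_POS convention; supply snp_file",
            snp_ids[!ok][1])
    snps <- data.frame(
      snp_id = snp_ids,
      chrom = as.integer(vapply(m, `[`, "", 2L)),
      pos = as.integer(vapply(m, `[`, "", 3L)),
      allele_ref = "A", allele_alt = "G", stringsAsFactors = FALSE)
  }
  genotype_matrix(dosage, snps, tab$line_id)
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))  # single-record VCF
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  bad <- grepl(",", alt, fixed = TRUE) | nchar(alt) != 1L | nchar(ref) != 1L
  if (any(bad))
    stopf("non-biallelic-SNP VCF record(s) rejected: %s",
          paste(sprintf("%s:%s", fix[bad, "CHROM"], fix[bad, "POS"]),
                collapse = ", "))
  chrom <- as.integer(sub("^[Cc]hr0*", "", fix[, "CHROM"]))
  if (anyNA(chrom)) stopf("cannot parse chromosome '%s' as an integer",
                          fix[which(is.na(chrom))[1], "CHROM"])
  pos <- as.integer(fix[, "POS"])
  ids <- fix[, "ID"]
  auto <- is.na(ids) | ids == "."
  ids[auto] <- sprintf("chr%02d_%d", chrom[auto], pos[auto])
  gt <- vcfR::extract.gt(vcf, element = "GT")
  # count ALT alleles; "./." and ".|." are missing
  count_alt <- function(s) {
    al <- strsplit(gsub("\\|", "/", s), "/", fixed = FALSE)
    vapply(al, function(a) {
      if (length(a) == 0L || anyNA(a) || any(a == ".")) NA_real_
      else sum(a == "1")
    }, numeric(1))
  }
  dosage <- apply(gt, 2L, count_alt)
  if (is.null(dim(dosage))) dosage <- matrix(dosage, nrow = 1L)
  dosage[is.na(gt)] <- NA_real_
  snps <- data.frame(snp_id = ids, chrom = chrom, pos = pos,
                     allele_ref = ref, allele_alt = alt,
                     stringsAsFactors = FALSE)
  genotype_matrix(t(dosage), snps, colnames(gt))
}

#' Write genotypes as a dosage TSV
#'
#' @param g a [genotype_matrix()].
#' @param path output file.
#' @param snp_file optional path for a SNP metadata sidecar
#'   (SNP/CHR/POS/REF/ALT) so alleles survive a round trip.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, snp_file = NULL) {
  d <- g$dosage
  body <- apply(d, 1L, function(r) {
    r <- ifelse(is.na(r), ".", as.character(as.integer(r)))
    paste(r, collapse = "\t")
  })
  lines <- c(paste(c("line_id", g$snps$snp_id), collapse = "\t"),
             paste(g$line_ids, body, sep = "\t"))
  writeLines(lines, path)
  if (!is.null(snp_file)) {
    st <- data.frame(SNP = g$snps$snp_id, CHR = g$snps$chrom,
                     POS = g$snps$pos, REF = g$snps$allele_ref,
                     ALT = g$snps$allele_alt)
    write.table(st, snp_file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read or write a long-format phenotype table
#'
#' Columns: `line_id`, `dataset_id` (population x environment), `trait`
#' (GPP/KGW/TP/YD), `value` (`.` for missing). `(line_id, dataset_id,
#' trait)` must be unique.
#'
#' @param path file path.
#' @return data.frame with the four columns; missing values are `NA`.
#' @export
read_phenotypes <- function(path) {
  ph <- read.delim(path, sep = "\t", na.strings = ".",
                   colClasses = c("character", "character", "character",
                                  "numeric"))
  validate_phenotypes(ph)
  ph
}

validate_phenotypes <- function(ph) {
  need <- c("line_id", "dataset_id", "trait", "value")
  if (!all(need %in% names(ph)))
    stopf("phenotype table must have columns %s", paste(need, collapse = ", "))
  bad <- !ph$trait %in% TRAITS
  if (any(bad)) stopf("unknown trait code '%s'", ph$trait[bad][1])
  key <- paste(ph$line_id, ph$dataset_id, ph$trait)
  if (anyDuplicated(key))
    stopf("duplicated (line_id, dataset_id, trait): %s", key[duplicated(key)][1])
  if (any(is.infinite(ph$value)))
    stopf("non-finite phenotype value for line %s",
          ph$line_id[is.infinite(ph$value)][1])
  invisible(ph)
}

#' @rdname read_phenotypes
#' @param ph phenotype data.frame.
#' @export
write_phenotypes <- function(ph, path) {
  validate_phenotypes(ph)
  out <- ph
  out$value <- fmt_num(ph$value)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

SUMSTAT_COLS <- c("SNP", "CHR", "POS", "A1", "A2", "BETA", "SE", "P", "N")

#' Read a GWAS summary-statistic table
#'
#' Expects the GCTA `.mlma`-like layout with columns
#' SNP/CHR/POS/A1/A2/BETA/SE/P/N (A1 = effect allele). Every row is
#' validated: `SE > 0` and `P` in `(0, 1]`.
#'
#' @param path TSV file.
#' @return data.frame of per-SNP association statistics.
#' @export
read_summary_stats <- function(path) {
  st <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(SUMSTAT_COLS %in% names(st)))
    stopf("summary-stat table %s lacks columns: %s", path,
          paste(setdiff(SUMSTAT_COLS, names(st)), collapse = ", "))
  validate_summary_stats(st)
  st
}

validate_summary_stats <- function(st) {
  if (nrow(st) == 0L) return(invisible(st))
  bad_se <- which(!is.finite(st$SE) | st$SE <= 0)
  if (length(bad_se))
    stopf("SE <= 0 or non-finite at row %d (SNP %s)", bad_se[1],
          st$SNP[bad_se[1]])
  bad_p <- which(!is.finite(st$P) | st$P <= 0 | st$P > 1)
  if (length(bad_p))
    stopf("P outside (0, 1] at row %d (SNP %s)", bad_p[1], st$SNP[bad_p[1]])
  invisible(st)
}

#' @rdname read_summary_stats
#' @param st summary-statistic data.frame.
#' @export
write_summary_stats <- function(st, path) {
  validate_summary_stats(st)
  out <- st[, intersect(c(SUMSTAT_COLS, setdiff(names(st), SUMSTAT_COLS)),
                        names(st))]
  for (cn in c("BETA", "SE", "P")) out[[cn]] <- fmt_num(st[[cn]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

META_COLS <- c(SUMSTAT_COLS, "K", "Q", "DF", "I2", "MODEL")

#' Read or write a meta-analysis statistics table
#'
#' The meta TSV extends the summary-stat layout with `K` (studies
#' combined), `Q`, `DF`, `I2` and `MODEL` (fixed/random).
#'
#' @param path TSV file.
#' @return data.frame of per-SNP meta statistics.
#' @export
read_meta_stats <- function(path) {
  st <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(META_COLS %in% names(st)))
    stopf("meta table %s lacks columns: %s", path,
          paste(setdiff(META_COLS, names(st)), collapse = ", "))
  validate_summary_stats(st)
  st
}

#' @rdname read_meta_stats
#' @param st meta-statistic data.frame.
#' @export
write_meta_stats <- function(st, path) {
  out <- st[, META_COLS]
  for (cn in c("BETA", "SE", "P", "Q", "I2")) out[[cn]] <- fmt_num(st[[cn]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Only records of type `gene` are retained; coordinates stay 1-based
#' inclusive as in GFF3. The gene id comes from the `ID` attribute and is
#' required.
#'
#' @param path GFF3 file.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `description` (from the `description` or `Note` attribute, else "").
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  if (length(gr) == 0L)
    return(data.frame(gene_id = character(), chrom = integer(),
                      start = integer(), end = integer(),
                      description = character(), stringsAsFactors = FALSE))
  ids <- gr$ID
  if (is.null(ids) || anyNA(ids))
    stopf("gene record without an ID attribute in %s", path)
  desc <- rep("", length(gr))
  for (cand in c("description", "Note")) {
    if (!is.null(gr@elementMetadata[[cand]])) {
      v <- as.character(gr@elementMetadata[[cand]])
      desc[desc == "" & !is.na(v)] <- v[desc == "" & !is.na(v)]
    }
  }
  chrom <- as.integer(sub("^[Cc]hr0*", "", as.character(GenomicRanges::seqnames(gr))))
  if (anyNA(chrom)) stopf("cannot parse a GFF3 seqid as an integer chromosome")
  data.frame(gene_id = as.character(ids), chrom = chrom,
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             description = desc, stringsAsFactors = FALSE)
}

INSTRUMENT_COLS <- c("SNP", "CHR", "POS", "BETA_X", "SE_X", "P_X",
                     "BETA_Y", "SE_Y", "P_Y")

#' Read or write an instrument table
#'
#' The machine-readable form of a published instrumental-variable table:
#' one row per SNP with exposure (`_X`) and outcome (`_Y`) effect size,
#' standard error and p-value.
#'
#' @param path TSV file.
#' @param exposure,outcome trait codes attached to the resulting set.
#' @return an [instrument_set()].
#' @export
read_instruments <- function(path, exposure, outcome = "YD") {
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(INSTRUMENT_COLS %in% names(tab)))
    stopf("instrument table %s lacks columns: %s", path,
          paste(setdiff(INSTRUMENT_COLS, names(tab)), collapse = ", "))
  instrument_set(exposure, outcome, tab[, INSTRUMENT_COLS])
}

#' @rdname read_instruments
#' @param s an [instrument_set()].
#' @export
write_instruments <- function(s, path) {
  out <- s$instruments[, INSTRUMENT_COLS]
  for (cn in c("BETA_X", "SE_X", "P_X", "BETA_Y", "SE_Y", "P_Y"))
    out[[cn]] <- fmt_num(s$instruments[[cn]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
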