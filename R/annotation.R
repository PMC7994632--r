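#' Candidate genes around a significant SNP
#'
#' Searches a window of `window_bp` on each side of the SNP. The distance
#' to a gene is 0 when the SNP falls inside the gene body, otherwise the
#' smaller of the distances to its ends. If any gene in the window belongs
#' to `curated_ids` (e.g. cloned yield genes), those genes are ranked
#' first; within each tier, genes are ordered nearest-first with the gene
#' id breaking ties.
#'
#' @param snp one-row data.frame (or list) with `chrom` and `pos`.
#' @param genes gene-model data.frame from [read_gff3()].
#' @param window_bp half-window in bp (default 200000, i.e. +/- 200 kb).
#' @param curated_ids optional character vector of prioritised gene ids.
#' @return data.frame of genes in the window with `distance_bp` and
#'   `curated` columns; empty when nothing is in range.
#' @export
candidate_genes <- function(snp, genes, window_bp = 200000,
                            curated_ids = NULL) {
  sel <- genes[genes$chrom == snp$chrom, , drop = FALSE]
  if (nrow(sel) == 0L) return(empty_candidates())
  inside <- snp$pos >= sel$start & snp$pos <= sel$end
  dist <- ifelse(inside, 0L,
                 pmin(abs(snp$pos - sel$start), abs(snp$pos - sel$end)))
  sel$distance_bp <- dist
  sel <- sel[dist <= window_bp, , drop = FALSE]
  if (nrow(sel) == 0L) return(empty_candidates())
  sel$curated <- sel$gene_id %in% curated_ids
  sel <- sel[order(!sel$curated, sel$distance_bp, sel$gene_id), , drop = FALSE]
  rownames(sel) <- NULL
  sel
}

empty_candidates <- function() {
  data.frame(gene_id = character(), chrom = integer(), start = integer(),
             end = integer(), description = character(),
             distance_bp = integer(), curated = logical(),
             stringsAsFactors = FALSE)
}

#' Annotate a table of significant SNPs
#'
#' Runs [candidate_genes()] for every row of a meta-statistic table and
#' keeps the top-ranked gene per SNP.
#'
#' @param snps meta- or summary-statistic data.frame (columns SNP, CHR,
#'   POS).
#' @param genes gene models from [read_gff3()].
#' @param window_bp,curated_ids see [candidate_genes()].
#' @return data.frame with one row per SNP that has a candidate.
#' @export
annotate_snps <- function(snps, genes, window_bp = 200000,
                          curated_ids = NULL) {
  rows <- lapply(seq_len(nrow(snps)), function(i) {
    hit <- candidate_genes(list(chrom = snps$CHR[i], pos = snps$POS[i]),
                           genes, window_bp, curated_ids)
    if (nrow(hit) == 0L) return(NULL)
    cbind(data.frame(SNP = snps$SNP[i], CHR = snps$CHR[i],
                     POS = snps$POS[i], stringsAsFactors = FALSE),
          hit[1, c("gene_id", "distance_bp", "curated", "description")])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(data.frame())
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out
}
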