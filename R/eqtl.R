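#' Read a per-tissue eQTL table
#'
#' Tab-separated with header; either explicit `chrom` + `pos` (1-based)
#' columns, or a GTEx-style `variant_id` of the form
#' `chrom_pos_ref_alt_build` (1-based position).
#'
#' @param path TSV file.
#' @param tissue one of [CARDIAC_TISSUES].
#' @return data.frame: `chrom`, `pos` (0-based base), `gene`, `tissue`.
#' @export
read_eqtl_table <- function(path, tissue) {
  tissue <- match.arg(tissue, CARDIAC_TISSUES)
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  if (all(c("chrom", "pos") %in% names(df))) {
    chrom <- df$chrom; pos1 <- as.numeric(df$pos)
  } else if ("variant_id" %in% names(df)) {
    parts <- strsplit(df$variant_id, "_")
    chrom <- vapply(parts, `[`, "", 1L)
    pos1 <- as.numeric(vapply(parts, `[`, "", 2L))
  } else {
    stop("eQTL table needs chrom/pos columns or a variant_id column: ", path,
         call. = FALSE)
  }
  gene <- if ("gene" %in% names(df)) df$gene else df[["gene_id"]]
  if (is.null(gene)) stop("eQTL table needs a gene or gene_id column: ", path,
                          call. = FALSE)
  data.frame(chrom = normalize_chrom(as.character(chrom)), pos = pos1 - 1,
             gene = gene, tissue = tissue, stringsAsFactors = FALSE)
}

#' Designate regulatory CHD-SNPs by eQTL intersection
#'
#' A focal enhancer SNP is a regulatory CHD-SNP (rCHD-SNP) iff its exact
#' base position appears in at least one cardiac-tissue eQTL table.
#' Matching is by position, not rsid; matches are deduplicated by
#' (variant, tissue, gene).
#'
#' @param calls enhancer call data.frame with `chrom`, `snp_start`, `rsid`.
#' @param eqtls data.frame from [read_eqtl_table()] (rbind over tissues).
#' @return list: `matches` (one row per variant x tissue x gene),
#'   `per_tissue` counts (a multi-tissue variant counts once per tissue),
#'   and `n_rchd_snps` (distinct variants).
#' @export
match_eqtls <- function(calls, eqtls) {
  key_call <- paste(calls$chrom, calls$snp_start)
  key_eqtl <- paste(eqtls$chrom, eqtls$pos)
  hit <- key_eqtl %in% key_call
  m <- eqtls[hit, , drop = FALSE]
  m$rsid <- calls$rsid[match(paste(m$chrom, m$pos), key_call)]
  m <- m[!duplicated(paste(m$chrom, m$pos, m$tissue, m$gene)), , drop = FALSE]
  m <- m[order(m$chrom, m$pos, m$tissue, m$gene), , drop = FALSE]
  rownames(m) <- NULL
  per_tissue <- table(factor(m$tissue[!duplicated(paste(m$chrom, m$pos, m$tissue))],
                             levels = CARDIAC_TISSUES))
  list(matches = m,
       per_tissue = c(per_tissue),
       n_rchd_snps = length(unique(paste(m$chrom, m$pos))))
}
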