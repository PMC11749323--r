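#' Region-based variant classification
#'
#' Assigns each variant one genomic region category against a gene model,
#' under the precedence
#' `exonic > promoter > intronic > ncrna_intronic > distal_intergenic`:
#'
#' * `exonic` — overlaps an exon of a protein-coding gene;
#' * `promoter` — within 1 kb upstream to 1 kb downstream of any TSS;
#' * `intronic` — inside a coding gene body but not exonic/promoter;
#' * `ncrna_intronic` — inside an ncRNA gene body (ncRNA exon hits are
#'   folded in here as well);
#' * `distal_intergenic` — everything else, including variants on
#'   chromosomes absent from the model (with a warning).
#'
#' Promoter deliberately overrides intronic: a variant inside one gene's
#' intron but within another gene's TSS +/- 1 kb is called promoter.
#'
#' @param variants data.frame with `chrom`, `start`, `end`.
#' @param model gene model from [read_gene_model()] (or the same structure
#'   built in code).
#' @param promoter_flank bp on each side of the TSS (default 1000).
#' @return the input with a `region_category` column appended.
#' @export
classify_location <- function(variants, model, promoter_flank = 1000L) {
  n <- nrow(variants)
  if (n == 0L) {
    variants$region_category <- character(0)
    return(variants)
  }
  genes <- model$genes
  exons <- model$exons
  coding_genes <- genes[genes$biotype == "coding", , drop = FALSE]
  ncrna_genes <- genes[genes$biotype == "ncRNA", , drop = FALSE]
  coding_exons <- exons[exons$gene %in% coding_genes$name, , drop = FALSE]

  # promoter: [tss - flank, tss + flank] inclusive -> half-open [a, b+1)
  promoters <- data.frame(
    chrom = genes$chrom,
    start = pmax(0, genes$tss - promoter_flank),
    end = genes$tss + promoter_flank + 1
  )

  hit_any <- function(regions) {
    out <- logical(n)
    if (nrow(regions)) out[unique(interval_overlaps(variants, regions)$a_idx)] <- TRUE
    out
  }
  in_exon <- hit_any(coding_exons)
  in_promoter <- hit_any(promoters)
  in_coding_body <- hit_any(coding_genes)
  in_ncrna_body <- hit_any(ncrna_genes)

  if (any(!variants$chrom %in% genes$chrom)) {
    warning("variant(s) on chromosome(s) absent from the gene model -> distal_intergenic",
            call. = FALSE)
  }
  category <- rep("distal_intergenic", n)
  category[in_ncrna_body] <- "ncrna_intronic"
  category[in_coding_body] <- "intronic"
  category[in_promoter] <- "promoter"
  category[in_exon] <- "exonic"
  variants$region_category <- category
  variants
}

#' Region category distribution
#'
#' @param annotated output of [classify_location()].
#' @return data.frame with `category`, `count`, `fraction` (fractions sum
#'   to 1).
#' @export
category_distribution <- function(annotated) {
  if (nrow(annotated) == 0L) stop("empty input", call. = FALSE)
  lvls <- c("exonic", "promoter", "intronic", "ncrna_intronic", "distal_intergenic")
  counts <- table(factor(annotated$region_category, levels = lvls))
  data.frame(category = lvls,
             count = as.integer(counts),
             fraction = as.numeric(counts) / nrow(annotated),
             stringsAsFactors = FALSE)
}
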