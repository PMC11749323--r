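#!/usr/bin/env Rscript
# Downstream characterisation of the called enhancers: phastCons contrast
# against 10,000 random noncoding 150 bp intervals (Wilcoxon rank-sum),
# conserved/ultra-conserved classification (>= 0.6 / >= 0.8), per-base
# phyloP SNP filter (>= 6.0), eQTL-based rCHD-SNP designation, and the
# FIMO-style motif scan with BH q <= 0.05.

suppressMessages(library(cardioreg))
dir.create("results", showWarnings = FALSE)
scn <- "scratch/scenario"

calls <- read.table("results/enhancer_calls.tsv", sep = "\t", header = TRUE,
                    comment.char = "", stringsAsFactors = FALSE)

## conservation ------------------------------------------------------------
phast <- read_track(file.path(scn, "phastcons.bedGraph"))
enh <- mean_conservation(calls[, c("chrom", "start", "end")], phast)
sizes <- read.table(file.path(scn, "genome.sizes"), header = TRUE, sep = "\t")
bg <- sample_background(setNames(sizes$size, sizes$chrom),
                        read_bed(file.path(scn, "exclusion.bed")),
                        n = 10000, length = 150, seed = 17)
bgc <- mean_conservation(bg, phast)
wt <- rank_sum_test(enh$mean_score, bgc$mean_score)
cls <- classify_conservation(enh$mean_score)
cat(sprintf("conservation: enhancers %.4f (SD %.4f) vs background %.4f (SD %.4f)\n",
            mean(enh$mean_score), sd(enh$mean_score),
            mean(bgc$mean_score), sd(bgc$mean_score)))
cat(sprintf("Wilcoxon rank-sum p = %.3g; conserved %d, ultra %d of %d\n",
            wt$p_value, sum(cls != "none"), sum(cls == "ultra"), nrow(enh)))

phylop <- read_track(file.path(scn, "phylop.bedGraph"))
snps <- unique(data.frame(chrom = calls$chrom, start = calls$snp_start,
                          end = calls$snp_start + 1,
                          rsid = calls$rsid, stringsAsFactors = FALSE))
conserved_snps <- filter_conserved_snps(snps, phylop, min_score = 6.0)
cat(sprintf("phyloP-conserved SNPs (>= 6.0): %d of %d\n",
            nrow(conserved_snps), nrow(snps)))

## eQTL --------------------------------------------------------------------
eqtls <- do.call(rbind, lapply(CARDIAC_TISSUES, function(t) {
  read_eqtl_table(file.path(scn, "eqtl", paste0(t, ".tsv")), t)
}))
rchd <- match_eqtls(calls, eqtls)
cat(sprintf("rCHD-SNPs: %d distinct (per tissue: %s)\n", rchd$n_rchd_snps,
            paste(names(rchd$per_tissue), rchd$per_tissue, collapse = ", ")))

## motifs ------------------------------------------------------------------
seqs <- read_fasta(file.path(scn, "enhancer_seqs.fasta"))
pfms <- read_jaspar_pfm(file.path(scn, "motifs.jaspar"))
pwms <- lapply(names(pfms), function(id) {
  build_pwm(pfms[[id]], motif_id = id, name = attr(pfms[[id]], "name"))
})
hits <- scan_motifs(seqs, pwms, p_threshold = 1e-4)
msig <- motif_significance(hits, q_threshold = 0.05)
cat(sprintf("significant motifs (q <= 0.05): %d; best: %s (q = %.3g)\n",
            length(unique(msig$motif_id[msig$significant])),
            msig$motif_id[1], msig$q_value[1]))

## tables ------------------------------------------------------------------
enh$conservation_class <- cls
write.table(enh, "results/enhancer_conservation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(
  metric = c("enh_mean", "enh_sd", "bg_mean", "bg_sd", "wilcoxon_p",
             "n_conserved", "n_ultra", "n_phylop_conserved", "n_rchd"),
  value = c(mean(enh$mean_score), sd(enh$mean_score), mean(bgc$mean_score),
            sd(bgc$mean_score), wt$p_value, sum(cls != "none"),
            sum(cls == "ultra"), nrow(conserved_snps), rchd$n_rchd_snps)),
  "results/conservation_summary.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)
write.table(rchd$matches, "results/rchd_snps.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(msig, "results/motif_significance.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
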