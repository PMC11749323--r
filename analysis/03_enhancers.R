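#!/usr/bin/env Rscript
# Enhancer calling: expand noncoding CHD-SNPs to 150 bp windows, intersect
# with the nine-stage x three-mark peak tracks at pvalSignal >= 9.0, merge
# identical windows across source catalogues, classify developmental stage
# categories and apply the benign-variant screen (benign ClinVar variants
# above star 1 inside a window drop the call).

suppressMessages(library(cardioreg))
dir.create("results", showWarnings = FALSE)
scn <- "scratch/scenario"

chd <- read.table("results/chd_variants.tsv", sep = "\t", header = TRUE,
                  comment.char = "", stringsAsFactors = FALSE)
nc <- chd[chd$region_category != "exonic" & chd$variant_type == "snp", ]
sizes <- read.table(file.path(scn, "genome.sizes"), header = TRUE, sep = "\t")
windows <- expand_windows(nc, chrom_sizes = setNames(sizes$size, sizes$chrom))
cat(sprintf("windows: %d from %d noncoding SNPs\n", nrow(windows), nrow(nc)))

peaks <- read_peak_dir(file.path(scn, "peaks"))
activity <- stage_activity(windows, peaks, threshold = 9.0)
calls <- call_enhancers(windows, activity, mark_rule = "any")
calls <- classify_stage_category(calls)
cat(sprintf("enhancer calls: %d\n", nrow(calls)))
print(table(calls$stage_category))

clinvar <- read_clinvar(file.path(scn, "clinvar_variants.tsv"))
kept <- exclude_benign(calls, clinvar)
cat(sprintf("after benign screen: %d (removed %d)\n",
            nrow(kept), nrow(calls) - nrow(kept)))

write.table(calls, "results/enhancer_calls.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(kept, "results/enhancer_calls_screened.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_bed(data.frame(chrom = kept$chrom, start = kept$start, end = kept$end,
                     name = kept$rsid, score = kept$max_signal, strand = "."),
          "results/enhancer_calls.bed")
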