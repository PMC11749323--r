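#!/usr/bin/env Rscript
# Catalogue filtering and region annotation: read the GWAS-catalog and
# ClinVar style tables, keep CHD-associated records (trait lexicon +
# p < 1e-5 for GWAS), tally variant types, classify genomic regions against
# the gene model and split coding from noncoding. Summary tables go to
# results/.

suppressMessages(library(cardioreg))
dir.create("results", showWarnings = FALSE)
scn <- "scratch/scenario"

gwas <- read_gwas_catalog(file.path(scn, "gwas_catalog.tsv"))
clinvar <- read_clinvar(file.path(scn, "clinvar_variants.tsv"))
chd <- filter_chd(rbind(gwas, clinvar))
cat(sprintf("CHD records: %d of %d input (GWAS %d, ClinVar %d)\n",
            nrow(chd), nrow(gwas) + nrow(clinvar),
            sum(chd$source == "gwas"), sum(chd$source == "clinvar")))

types <- classify_variant_types(chd)
print(types)

model <- read_gene_model(file.path(scn, "genes.gff3"))
chd <- classify_location(chd, model)
dist <- category_distribution(chd)
print(dist)

parts <- split_coding_noncoding(chd)
cat(sprintf("coding %d / noncoding %d\n", nrow(parts$coding), nrow(parts$noncoding)))

write.table(data.frame(metric = c("n_chd", "n_gwas", "n_clinvar",
                                  "n_coding", "n_noncoding"),
                       value = c(nrow(chd), sum(chd$source == "gwas"),
                                 sum(chd$source == "clinvar"),
                                 nrow(parts$coding), nrow(parts$noncoding))),
            "results/snp_counts.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
write.table(dist, "results/region_distribution.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(chd, "results/chd_variants.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
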