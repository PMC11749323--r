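#!/usr/bin/env Rscript
# Coding branch: build the physical-interaction network over genes carrying
# exonic CHD-SNPs, partition it with MCL (inflation 2.0), and classify
# mutations by |ddG| >= 1.5 kcal/mol. Runs on the synthetic complex and
# ddG table, then repeats the ranking on the packaged MYBPC3-ACTC1 table.

suppressMessages(library(cardioreg))
dir.create("results", showWarnings = FALSE)
scn <- "scratch/scenario"

chd <- read.table("results/chd_variants.tsv", sep = "\t", header = TRUE,
                  comment.char = "", stringsAsFactors = FALSE)
coding <- chd[chd$region_category == "exonic", ]
model <- read_gene_model(file.path(scn, "genes.gff3"))
coding_exons <- model$exons[model$exons$gene %in%
                              model$genes$name[model$genes$biotype == "coding"], ]
ov <- interval_overlaps(coding, coding_exons)
query <- sort(unique(coding_exons$gene[ov$b_idx]))
cat(sprintf("query genes with exonic CHD-SNPs: %d\n", length(query)))

edges <- read.table(file.path(scn, "ppi_edges.tsv"), sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
nw <- build_network(query, edges)
cl <- mcl(nw, inflation = 2.0)
summ <- cluster_summary(cl, nw)
cat(sprintf("network: %d nodes (%d added), %d edges -> %d clusters\n",
            nrow(nw$nodes), sum(nw$nodes$origin == "added"),
            nrow(nw$edges), cl$n_clusters))
print(summ$clusters)

## mutation impact ---------------------------------------------------------
muts <- read_mutation_table(file.path(scn, "ddg_synthetic.tsv"))
ranked <- rank_mutations(muts, threshold = 1.5)
atoms <- read_pdb_atoms(file.path(scn, "complex.pdb"))
iface <- detect_interface(atoms, "A", "B", cutoff = 5.0)
top <- ranked[1, ]
cat(sprintf("synthetic complex: %d interface residues of %d\n",
            sum(iface$interface), nrow(iface)))
cat(sprintf("top mutation %s (ddG %.2f), %d heavy-atom contacts\n",
            top$mutation, top$ddg,
            count_contacts(atoms, top$mutated_chain, top$position)))

## packaged curated table ---------------------------------------------------
t2 <- read_mutation_table(system.file("extdata", "mybpc3_actc1_ddg.tsv",
                                      package = "cardioreg"))
r2 <- rank_mutations(t2, threshold = 1.5)
cat(sprintf("curated MYBPC3-ACTC1 table: max ddG %.2f (%s), %d deleterious of %d\n",
            attr(r2, "summary")$max_ddg, r2$mutation[1],
            attr(r2, "summary")$n_deleterious, attr(r2, "summary")$n))

write.table(data.frame(gene = names(cl$partition),
                       cluster = unname(cl$partition)),
            "results/clusters.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
write.table(summ$clusters, "results/cluster_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(ranked, "results/mutations_ranked_synthetic.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(r2, "results/mutations_ranked_mybpc3_actc1.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
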