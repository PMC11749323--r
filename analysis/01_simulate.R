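#!/usr/bin/env Rscript
# Generate the default synthetic study scenario (seed 17): a toy 3.5 Mb
# two-chromosome genome with 300 planted enhancer windows, decoy SNPs,
# conservation and peak tracks, eQTL tables, a motif set, an interaction
# network and a toy protein complex. Raw inputs land under scratch/scenario;
# the planted-truth manifest is the reference for every downstream script.

suppressMessages(library(cardioreg))

manifest <- generate_scenario("scratch/scenario", seed = 17)

cat("Scenario written to scratch/scenario\n")
cat(sprintf("  planted enhancer windows : %d\n", nrow(manifest$planted_enhancers)))
cat(sprintf("  decoy noncoding SNPs     : %d\n", nrow(manifest$noise_snps)))
cat(sprintf("  coding (exonic) SNPs     : %d\n", nrow(manifest$coding_snps)))
cat(sprintf("  planted rCHD-SNPs        : %d\n", manifest$n_rchd_snps))
cat(sprintf("  planted network clusters : %d\n",
            length(manifest$params$clique_sizes)))
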