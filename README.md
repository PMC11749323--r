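# cardioreg

Integrative analysis of congenital-heart-disease (CHD) associated SNPs, for
researchers studying how noncoding variants disrupt cardiac gene regulation
and how coding variants destabilise protein complexes.

Most CHD-associated variants are noncoding. The noncoding branch of this
package expands each CHD-SNP into a 150 bp window
(`[snp − 75, snp + 75)`), calls the window a putative cardiac enhancer when
it intersects a histone-mark peak (H3K27ac / H3K4me1 / H3K4me3, narrowPeak
`pvalSignal ≥ 9.0`) in any of nine Carnegie stages of human heart
organogenesis (CS13–CS23), and classifies its developmental activity from
the stage groups E = {CS13,14,16}, I = {CS17–19}, L = {CS20,21,23}
(early / intermediate / late / pairwise combinations / always-active).
Called enhancers are then characterised by:

* **conservation** — mean phastCons with uncovered bases as 0, classified
  conserved (≥ 0.6) or ultra-conserved (≥ 0.8), contrasted against 10,000
  random noncoding 150 bp intervals with a two-sided Wilcoxon rank-sum
  test; per-SNP phyloP ≥ 6.0 flags conserved variants;
* **motif content** — a FIMO-style PWM scan with exact p-values from a
  discretised convolution of the null score distribution and
  Benjamini-Hochberg q ≤ 0.05 across the full scan universe;
* **eQTL overlap** — SNPs whose positions occur in cardiac-tissue eQTL
  tables (aorta, coronary artery, atrial appendage, left ventricle) are
  designated regulatory CHD-SNPs (rCHD-SNPs).

The coding branch builds a physical-interaction network over genes with
exonic CHD-SNPs, partitions it with a from-scratch Markov Cluster (MCL)
implementation (inflation 2.0), and classifies missense mutations by the
change in complex binding free energy,

    ΔG_bind = G_AB − G_A − G_B,      ΔΔG = ΔG_bind^mut − ΔG_bind^WT,

calling a mutation deleterious when |ΔΔG| ≥ 1.5 kcal/mol. Interface
residues are detected with a 5 Å heavy-atom distance rule on a two-chain
complex and residue contacts counted at 4 Å.

A seeded synthetic-data generator (`generate_scenario()`) emulates every
input format at toy scale — catalogue TSVs, 27 narrowPeak tracks,
conservation tracks, eQTL tables, a JASPAR motif file, an edge list, a toy
PDB complex and a ΔΔG table — with every planted truth in a manifest, so
the full pipeline runs and is tested entirely offline.

## Worked example

The numbered scripts under `analysis/` run the whole study on the default
synthetic scenario (seed 17):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_snp_catalog.R
Rscript analysis/03_enhancers.R
Rscript analysis/04_conservation_motifs_eqtl.R
Rscript analysis/05_ppin_structure.R
```

which prints, among other things:

```
CHD records: 442 of 479 input (GWAS 296, ClinVar 146)
coding 30 / noncoding 412
enhancer calls: 300
after benign screen: 290 (removed 10)
conservation: enhancers 0.2173 (SD 0.2202) vs background 0.0869 (SD 0.1284)
Wilcoxon rank-sum p = 9.76e-34; conserved 24, ultra 6 of 300
rCHD-SNPs: 60 distinct (per tissue: Aorta 18, Coronary_Artery 18, ...)
significant motifs (q <= 0.05): 1; best: SYNM001.1 (q = 0.00139)
network: 33 nodes (3 added), 125 edges -> 3 clusters
curated MYBPC3-ACTC1 table: max ddG 1.64 (R419H), 1 deleterious of 15
```

Reading the output: all 300 planted enhancer windows are recovered with no
false calls (the 8.9-signal near-miss stays out); the benign screen removes
exactly the 10 windows harbouring 2-star benign variants; the planted
conservation contrast (0.21 vs 0.08) is decisively detected; the 60 planted
eQTL SNPs are designated rCHD-SNPs; only the planted motif survives the
q-filter; MCL recovers the three planted modules; and the packaged
MYBPC3-ACTC1 mutation table yields R419H (ΔΔG 1.64 kcal/mol) as the single
deleterious mutation. Summary tables land under `results/`.

The same run is available programmatically:

```r
library(cardioreg)
generate_scenario("scenario", seed = 17)
report <- run_pipeline(pipeline_config("scenario", seed = 1), out_dir = "out")
```

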