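---
title: "Methods: stage-resolved cardiac enhancer calling and coding-variant impact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stage-resolved cardiac enhancer calling and coding-variant impact}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

Congenital heart disease (CHD) associates with thousands of SNPs, most of
them noncoding. `cardioreg` implements a two-branch analysis over such
variants. The noncoding branch asks whether a SNP's immediate sequence
context behaves like a developmental cardiac enhancer: it expands each SNP
into a fixed window, intersects the window with histone-mark peaks across
nine Carnegie stages of human heart organogenesis, classifies when in
development the putative element is active, and then characterises the
called elements by evolutionary conservation, transcription-factor motif
content and cardiac eQTL overlap. The coding branch asks whether exonic
SNPs can disrupt protein complexes: it clusters a physical-interaction
network over the affected genes and classifies missense mutations by their
change in binding free energy on a resolved two-chain complex.

Everything below is computed by the package; the numbers quoted are the
ones its tests and scripts themselves produce.

# Coordinate convention

All internal coordinates are 0-based, half-open (BED convention). 1-based
inputs — GWAS-catalogue positions, ClinVar start/stop, GFF3, fixedStep
wiggle headers, GTEx-style `variant_id` strings — are converted at parse
time and never afterwards. Under this convention the default window
arithmetic is exact: a SNP occupying `chr1:[236688982, 236688983)` expanded
by the default flank gives `chr1:[236688907, 236689057)`, a 150 bp element.
This is also why the window is `[snp - 75, snp + 75)` and not
"75 + 1 + 75 = 151": only the half-open reading yields a 150 bp element
whose focal base sits at offset 75.

# Catalogue filtering

A variant is CHD-associated when any of its trait strings contains (case-
insensitive substring, whitespace-normalised) a phrase from the CHD trait
lexicon. GWAS records additionally require an association p-value strictly
below `p_threshold`; clinically curated (ClinVar-style) records are kept on
the trait match alone, since they carry review classifications rather than
association p-values. The default threshold is `1e-5`, the literal value of
the "10e−6" convention used in GWAS-catalogue-style filtering; `1e-6` is a
single argument away for users who read that notation as 10^−6^.
Deduplication is by (rsid, interval, source), keeping the smallest p-value
within a source; the same variant arriving from both catalogues is kept
twice on purpose, because the two sources are windowed separately and
merged later at the enhancer level, preserving provenance.

ClinVar review-status text maps onto the 0-4 star scale with the standard
table (practice guideline = 4, expert panel = 3, multiple submitters
without conflicts = 2, single submitter or conflicting = 1, no assertion
= 0).

# Region annotation

A deliberately small region classifier stands in for a full annotation
engine: categories are `exonic`, `promoter` (TSS ± 1 kb, strand-aware),
`intronic`, `ncrna_intronic` and `distal_intergenic`, resolved with that
precedence. Two decisions were genuinely open:

* a variant inside one gene's intron but within another gene's TSS ± 1 kb
  is called `promoter` — the more specific regulatory call wins;
* exon hits in ncRNA genes fold into `ncrna_intronic`, since the category
  scheme has no ncRNA-exonic bucket.

Splice-site and UTR subcategories are intentionally not modelled. The
coding/noncoding split is then `{exonic}` versus everything else, an
exhaustive disjoint partition.

# Enhancer calling

Each noncoding SNP becomes a 150 bp window (flank 75 bp each side, clipped
at chromosome bounds with a `truncated` flag). A (stage, mark) cell is
active when any peak of that track overlaps the window by ≥ 1 bp with
`pvalSignal >= 9.0` — inclusive, pinned by an 8.9 near-miss fixture. The
`pvalSignal` is narrowPeak column 8 (the −log10 p-value); the column index
is configurable because track hubs disagree about whether column 7 or 8
carries the score.

A stage counts as active under the default `mark_rule = "any"` when any of
H3K27ac, H3K4me1, H3K4me3 passes. Conjunction ("all") would demand
promoter-typical H3K4me3 on every enhancer, which contradicts how these
marks distribute; it remains available, as do single-mark rules. A window
is called an enhancer when at least one stage is active. Calls with
byte-identical intervals from the two source catalogues merge into one call
with combined provenance; near-identical overlapping windows from distinct
SNPs deliberately stay distinct, because elements are counted per focal
SNP.

Stage categories use the groups E = {CS13, CS14, CS16},
I = {CS17, CS18, CS19}, L = {CS20, CS21, CS23}: the category is read off
the set of groups *fully contained* in the active stage set — one group
gives early/intermediate/late, two give the pairwise categories, all three
give `always_active`, none gives `unclassified`. An optional pre-filter
(`min_stages`) restricted to calls active in ≥ 5 stages is available but
off by default. The benign screen removes a call when a benign-classified
variant with review status above one star (≥ 2 stars) falls inside the
interval; a 1-star benign fixture pins the boundary. Conservation, motif
and eQTL analyses run on the full merged call set — the screen produces a
separate, more conservative deliverable.

# Conservation

Element-level conservation is the mean per-base phastCons score over the
interval with uncovered bases counted as zero (the "mean0" semantics of
`bigWigAverageOverBed`). Unalignable bases carry no evidence of
conservation, and treating them as missing would inflate means; a
covered-only mean is available as an option. Classification is
`conserved` at mean ≥ 0.6 and `ultra` at ≥ 0.8, both inclusive. Per-SNP
conservation uses phyloP at the focal base with an inclusive 6.0 cutoff;
uncovered bases are dropped with a warning rather than scored 0, because a
missing base in a per-base track is a coverage gap, not evidence.

The background is 10,000 random 150 bp intervals drawn uniformly from the
genome by rejection sampling against an exclusion set of coding exons and
assembly gaps only ("noncoding genome"); repeats are not excluded and
background intervals may overlap each other. The draw is seeded and
reproducible. The two distributions are compared with a two-sided Wilcoxon
rank-sum test — exact enumeration when the smaller sample has ≤ 8
observations and there are no ties, otherwise the normal approximation
with tie and continuity corrections. The implementation wraps
`stats::wilcox.test` and is pinned in the tests against a full
permutation-enumeration oracle for all n = m ≤ 6 no-tie inputs.

# Motif scanning

PWMs are built from JASPAR-style count matrices as
`log2((counts + pc * bg) / (total + pc) / bg)` with pseudocount 0.1 (the
FIMO convention) and a 0-order background estimated from the scanned
sequences unless supplied. Scores are discretised on a 1/1000-bit grid and
the null score distribution is built by convolving per-column distributions
under the background — the same dynamic programme FIMO uses — so per-hit
p-values `P(score >= s)` are exact at grid resolution. The tests verify the
distribution against exhaustive 4^L enumeration for L ≤ 5 and check that
halving the grid step moves p-values by < 5% relative.

Both strands are scanned; `N` bases contribute the background-expected
column score. Multiple testing is corrected with Benjamini-Hochberg across
**all** scanned (motif, position, strand) tests, and a motif's q-value in a
region is the q of its best hit. An alternative — adjusting only the
per-(motif, region) best hits — was considered and rejected: best-hit
p-values are minima over hundreds of positions, so that universe makes
random decoy motifs significant by construction. Adjusting over the full
scan universe is also what FIMO reports. Motifs survive at q ≤ 0.05
(inclusive).

# eQTL designation

A focal enhancer SNP is a regulatory CHD-SNP (rCHD-SNP) when its exact base
position occurs in at least one cardiac-tissue eQTL table (aorta, coronary
artery, atrial appendage, left ventricle). Matching is positional, not by
rsid, and allele concordance is not checked — the designation mirrors a
coordinate intersection. Both summaries are emitted: distinct variants, and
per-tissue counts in which a multi-tissue variant counts once per tissue
(so per-tissue totals can exceed the distinct count).

# Network clustering

The interaction network restricts a physical-interaction edge list to edges
touching at least one query gene (genes with exonic CHD-SNPs); non-query
endpoints are retained and flagged `added`, isolated query genes stay as
singletons, and self-loops are rejected. Edge inference itself (GeneMania-
style label propagation) is out of scope — edges are inputs.

The Markov Cluster algorithm is implemented from scratch in dense base-R
linear algebra: add self-loops of weight 1, column-normalise, then iterate
expansion (matrix power 2) and inflation (elementwise power, default 2.0,
then column renormalisation), pruning entries below 1e-6 and renormalising,
until the largest entry change drops below 1e-8 or 100 iterations. In the
limit matrix, rows with non-zero diagonal are attractors; each node joins
every attractor it flows to, and overlapping attractor systems are unioned
(connected components of the attractor-membership graph) so the partition
is disjoint. Cluster ids are dense from 1 in decreasing size order.
Inflation is the granularity dial; 2.0 is the conventional default and the
planted-partition suite (3 × 10 nodes, p_in = 0.9, p_out = 0.02) is
recovered exactly in ≥ 95 of 100 seeds at that setting.

# Mutation impact

The energy bookkeeping is two compositional identities:
`dG_bind = G_AB − G_A − G_B` and `ddG = dG_bind^mut − dG_bind^WT`
(kcal/mol). ddG values arrive from an external predictor's output table;
the package deliberately does not model energies. A mutation is deleterious
when `|ddG| >= 1.5` kcal/mol, inclusive on both signs. Because
surface-area-based interface tools are outside this package's dependency
set, interface residues are detected with a distance rule: a residue is at
the interface when any of its heavy atoms lies within 5.0 Å (inclusive) of
any heavy atom of the partner chain — a PISA-like convention; residue
contact counting uses 4.0 Å. Both cutoffs are arguments. The packaged
MYBPC3-ACTC1 table of 15 curated mutations reproduces the expected
analysis: maximum ddG 1.64 (R419H), exactly one deleterious record, and
that record not at the interface.

# The synthetic scenario

`generate_scenario()` writes every input the pipeline reads, at toy scale,
with all truths in a manifest. It emulates the *statistical contrasts* the
method depends on, not the human genome: a 2-chromosome ~3.5 Mb genome with
a grid gene model, 300 planted enhancer windows spread over the seven stage
categories with peak signal ~ U(10, 15) in exactly their category's stages
(H3K27ac and H3K4me1), background peaks at U(3, 8), decoy SNPs with no
signal, and near-miss fixtures one notch outside every threshold
(pvalSignal 8.9, GWAS p exactly at threshold, benign 1-star, phyloP 5.9).

Per-region conservation means are drawn from Beta distributions
moment-matched to the cardiac-enhancer contrast (mean 0.2143, SD 0.2243
for enhancers; mean 0.08264, SD 0.1501 for background). A truncated normal
cannot reproduce those moments — truncating a normal with mean 0.083 and SD
0.15 at zero shifts its mean to ~0.15 — whereas the Beta match is exact on
[0, 1], which is what makes the "sample means within 3 SE of the planted
values" recovery check meaningful. A pleasant side effect of the matched
enhancer Beta is that ~8% of planted windows exceed the 0.6 conserved
cutoff and ~2% the 0.8 ultra cutoff, the same order as the fractions
observed in real cardiac enhancer sets.

The planted motif is a 12-column high-information PWM with one sampled
instance per sequence; decoys are 6-column low-information PFMs. The decoy
length is a design guarantee, not a tuning: under a uniform background the
best possible 6-mer match has p ≥ 4^−6 ≈ 2.4e-4, above the 1e-4 scan
threshold, so decoys cannot reach significance while 12-column planted
instances sit orders of magnitude below it. The network is a 3 × 10
planted-partition graph (p_in 0.9, p_out 0.02) over the query genes plus
three externally attached "added" genes, and the ddG table plants exactly
one record beyond ±1.5.

Scale was chosen once: 300 planted windows against the study-scale 10,000
background intervals gives the rank-sum contrast a comfortable margin
(analytically, AUC ≈ 0.70 gives z ≈ 11 at these sizes) while keeping the
whole pipeline run around ten seconds. What passing recovery shows is that
the machinery is correct under the planted contrasts; it does not show
robustness to LD structure, GC composition, repeat content or peak-caller
artefacts, none of which the toy genome models.

# Numerical choices and degenerate inputs

* Score grid 1/1000 bits; MCL pruning 1e-6, convergence 1e-8, cap 100
  iterations (non-convergence returns the current clustering with a
  warning flag).
* All biological thresholds are inclusive at the boundary (9.0, 0.6, 0.8,
  6.0, ±1.5, q = 0.05, stars ≥ 2); the GWAS p-value filter is strict
  (`<`).
* Flank 0 degenerates to the 1 bp SNP window and is flagged; windows
  clipped at chromosome bounds are flagged `truncated`.
* Overlapping conservation-track intervals resolve last-wins with a
  warning; uncovered bases are `NA` at the query layer so that mean0 and
  covered-only semantics stay distinguishable.
* Identical constant samples short-circuit the rank-sum test to p = 1.
* Ranking ties in the mutation table break by signed ddG descending, then
  lexicographic label, making the order a stable total order.

# Known limitations

The region classifier has no splice/UTR resolution; enhancer calls are
per-SNP windows, not merged regulatory domains, so adjacent SNPs can yield
near-duplicate calls by design; binding energies are consumed, not
computed; the distance-based interface rule approximates buried-surface
criteria and can disagree with them near the cutoff; and the synthetic
scenario's genome is deliberately minimal, as discussed above.
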