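#' Default synthetic scenario parameters
#'
#' The toy study conditions: a 2-chromosome ~3.5 Mb genome, 300 planted
#' enhancer windows across the seven stage categories, 50 decoy noncoding
#' SNPs, per-region conservation drawn from Beta distributions moment-matched
#' to the cardiac-enhancer contrast (mean 0.2143, SD 0.2243 for enhancers;
#' mean 0.08264, SD 0.1501 for random noncoding background), a 20% eQTL
#' overlap fraction, a 3 x 10-clique planted interaction network
#' (p_in = 0.9, p_out = 0.02), and one mutation beyond the +/-1.5 kcal/mol
#' deleteriousness boundary.
#'
#' @param ... overrides for the listed defaults.
#' @return named list of parameters.
#' @export
scenario_params <- function(...) {
  p <- list(
    genome = c(chr1 = 2000000, chr2 = 1500000),
    n_coding_genes = 30L,
    n_ncrna_genes = 8L,
    category_mix = c(early = 60L, intermediate = 60L, late = 60L,
                     early_intermediate = 30L, early_late = 30L,
                     intermediate_late = 30L, always_active = 30L),
    n_noise_snps = 50L,
    flank = 75L,
    planted_signal = c(10, 15),
    background_signal = c(3, 8),
    background_peaks_per_track = 150L,
    cons_enh = c(mean = 0.2143, sd = 0.2243),
    cons_bg = c(mean = 0.08264, sd = 0.1501),
    eqtl_fraction = 0.2,
    n_benign_excluded = 10L,
    n_phylop_conserved = 20L,
    p_threshold = 1e-5,
    n_motif_seqs = 10L,
    motif_seq_len = 200L,
    n_decoy_motifs = 5L,
    clique_sizes = c(10L, 10L, 10L),
    p_in = 0.9,
    p_out = 0.02
  )
  dots <- list(...)
  p[names(dots)] <- dots
  n_planted <- sum(p$category_mix)
  if (n_planted < 1L) stop("category_mix must plant at least one enhancer", call. = FALSE)
  if (p$n_benign_excluded >= n_planted) {
    stop("more benign-excluded windows than planted enhancers", call. = FALSE)
  }
  if (p$n_phylop_conserved > n_planted) {
    stop("more phyloP-conserved SNPs than planted enhancers", call. = FALSE)
  }
  p
}

# Beta shape parameters matching a given mean and sd on [0, 1].
beta_shape <- function(mean, sd) {
  mean <- unname(mean); sd <- unname(sd)
  v <- sd^2
  if (v >= mean * (1 - mean)) stop("infeasible Beta moments", call. = FALSE)
  nu <- mean * (1 - mean) / v - 1
  c(a = mean * nu, b = (1 - mean) * nu)
}

#' Planted-partition interaction graph
#'
#' Erdos-Renyi blocks: within-cluster edges with probability `p_in`,
#' between-cluster edges with probability `p_out`.
#'
#' @param seed integer seed, or `NULL` to draw from the current RNG stream.
#' @param sizes cluster sizes.
#' @param p_in,p_out edge probabilities.
#' @param node_names optional names (defaults `N01`, `N02`, ...).
#' @return list: `edges` (geneA, geneB, interaction_type = "physical"),
#'   `membership` (named integer vector).
#' @export
gen_planted_graph <- function(seed = NULL, sizes = c(10L, 10L, 10L),
                              p_in = 0.9, p_out = 0.02, node_names = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- sum(sizes)
  if (is.null(node_names)) node_names <- sprintf("N%02d", seq_len(n))
  stopifnot(length(node_names) == n)
  membership <- stats::setNames(rep(seq_along(sizes), sizes), node_names)
  pairs <- utils::combn(n, 2)
  same <- membership[pairs[1, ]] == membership[pairs[2, ]]
  keep <- stats::runif(ncol(pairs)) < ifelse(same, p_in, p_out)
  edges <- data.frame(geneA = node_names[pairs[1, keep]],
                      geneB = node_names[pairs[2, keep]],
                      interaction_type = "physical", stringsAsFactors = FALSE)
  list(edges = edges, membership = membership)
}

#' Planted-motif sequence set
#'
#' Random uniform-background sequences, each carrying one instance sampled
#' from a high-information 12-column planted PWM at a random offset and
#' strand, plus short low-information decoy PFMs that are absent from the
#' sequences. The decoys are 6 columns long: under a uniform background the
#' best possible 6-mer match has p >= 4^-6, so decoys cannot reach the
#' significance range of planted instances by construction.
#'
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @param n_seqs,seq_len sequence count and length.
#' @param n_decoys number of decoy motifs.
#' @return list: `pfms` (planted first), `sequences`, `planted_id`,
#'   `truth` (seq_name, offset, strand).
#' @export
gen_motif_set <- function(seed = NULL, n_seqs = 10L, seq_len = 200L,
                          n_decoys = 5L) {
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  consensus <- c("T", "G", "A", "C", "G", "T", "C", "A", "T", "G", "C", "A")
  L <- length(consensus)
  planted <- matrix(1, 4, L, dimnames = list(bases, NULL))
  planted[cbind(match(consensus, bases), seq_len(L))] <- 18
  attr(planted, "name") <- "synTF1"
  pfms <- list(SYNM001.1 = planted)
  for (d in seq_len(n_decoys)) {
    cnt <- vapply(seq_len(6L), function(i) {
      tabulate(sample.int(4L, 20L, replace = TRUE), 4L)
    }, numeric(4))
    rownames(cnt) <- bases
    attr(cnt, "name") <- sprintf("synDecoy%d", d + 1L)
    pfms[[sprintf("SYNM%03d.1", d + 1L)]] <- cnt
  }
  probs <- sweep(planted, 2, colSums(planted), "/")
  seqs <- character(n_seqs)
  truth <- data.frame(seq_name = sprintf("enh_seq%02d", seq_len(n_seqs)),
                      offset = NA_integer_, strand = NA_character_,
                      stringsAsFactors = FALSE)
  for (s in seq_len(n_seqs)) {
    bg <- sample(bases, seq_len, replace = TRUE)
    inst <- vapply(seq_len(L), function(i) sample(bases, 1L, prob = probs[, i]),
                   character(1))
    offset <- sample.int(seq_len - L - 40L, 1L) + 19L  # keep clear of the ends
    strand <- sample(c("+", "-"), 1L)
    placed <- if (strand == "+") inst else {
      rev(chartr("ACGT", "TGCA", inst))
    }
    bg[offset + seq_len(L)] <- placed
    seqs[s] <- paste(bg, collapse = "")
    truth$offset[s] <- offset
    truth$strand[s] <- strand
  }
  names(seqs) <- truth$seq_name
  list(pfms = pfms, sequences = seqs, planted_id = "SYNM001.1", truth = truth)
}

#' Deterministic toy two-chain complex
#'
#' Two short peptide chains laid out so that the first two residues of
#' chain B sit within 5 angstroms of chain A (interface by the distance
#' rule) while the rest are far apart.
#'
#' @return heavy-atom data.frame in the [read_pdb_atoms()] layout.
#' @export
toy_complex_atoms <- function() {
  res_atoms <- function(chain, resno, resid, cx, cy, cz) {
    # N, CA, C, O, CB in a compact local arrangement
    data.frame(chain = chain, resno = resno, resid = resid,
               elety = c("N", "CA", "C", "O", "CB"),
               x = cx + c(-1.2, 0, 1.2, 2.0, 0),
               y = cy + c(0.5, 0, 0.5, 0, -1.4),
               z = cz + c(0, 0, 0, 0.8, 0.4),
               stringsAsFactors = FALSE)
  }
  a <- do.call(rbind, lapply(1:8, function(i) {
    res_atoms("A", i, "ALA", (i - 1) * 5.5, 0, 0)
  }))
  b <- do.call(rbind, lapply(1:6, function(j) {
    near <- j <= 2
    res_atoms("B", j, "GLY", (j - 1) * 5.5, if (near) 4.0 else 30.0, 0)
  }))
  rbind(a, b)
}

#' Write atoms as PDB ATOM records
#'
#' @param atoms data.frame in the [read_pdb_atoms()] layout.
#' @param path output file.
#' @export
write_pdb <- function(atoms, path) {
  elem <- substr(gsub("[0-9]", "", atoms$elety), 1, 1)
  lines <- sprintf(
    "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(atoms)), atoms$elety, atoms$resid, atoms$chain, atoms$resno,
    atoms$x, atoms$y, atoms$z, 1.00, 0.00, elem)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate the full synthetic scenario on disk
#'
#' Writes every input the pipeline reads — GWAS-catalog and ClinVar style
#' tables, nine-stage x three-mark narrowPeak tracks, phastCons and phyloP
#' tracks, per-tissue eQTL tables, a JASPAR motif file and FASTA sequence
#' set, a physical-interaction edge list, a toy two-chain PDB complex, a
#' ddG table, a GFF3 gene model, chromosome sizes and an exclusion BED —
#' together with a machine-readable manifest of every planted truth.
#' Output is byte-identical for a fixed seed.
#'
#' Near-miss fixtures pin boundary semantics: a peak at pvalSignal 8.9
#' under one decoy window, a GWAS record at exactly the significance
#' threshold, a benign 1-star variant inside a window, and a phyloP score
#' of 5.9 at one SNP.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed (default 17).
#' @param params parameter list from [scenario_params()].
#' @return the manifest list, invisibly; also written as `manifest.json`.
#' @export
generate_scenario <- function(out_dir, seed = 17L, params = scenario_params()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "peaks"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "eqtl"), showWarnings = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  genome <- params$genome
  flank <- params$flank

  ## ---- gene model -------------------------------------------------------
  cg <- params$n_coding_genes
  genes <- data.frame(
    name = sprintf("GENE%02d", seq_len(cg)),
    chrom = "chr1",
    start = 20000 + (seq_len(cg) - 1) * 32000,
    strand = ifelse(seq_len(cg) %% 2 == 1, "+", "-"),
    biotype = "coding", stringsAsFactors = FALSE)
  genes$end <- genes$start + 15000
  ng <- params$n_ncrna_genes
  nc <- data.frame(
    name = sprintf("NCRNA%02d", seq_len(ng)),
    chrom = "chr2",
    start = 20000 + (seq_len(ng) - 1) * 30000,
    strand = "+", biotype = "ncRNA", stringsAsFactors = FALSE)
  nc$end <- nc$start + 12000
  genes <- rbind(genes, nc)
  exon_offsets <- list(c(0, 500), c(4000, 4800), c(8000, 8800), c(14200, 15000))
  exons <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    offs <- if (genes$biotype[i] == "coding") exon_offsets else exon_offsets[1:2]
    do.call(rbind, lapply(offs, function(o) {
      data.frame(gene = genes$name[i], chrom = genes$chrom[i],
                 start = genes$start[i] + o[1],
                 end = min(genes$start[i] + o[2], genes$end[i]),
                 stringsAsFactors = FALSE)
    }))
  }))
  gff <- c(
    sprintf("%s\tcardioreg_sim\tgene\t%d\t%d\t.\t%s\t.\tID=%s;biotype=%s",
            genes$chrom, genes$start + 1, genes$end, genes$strand,
            genes$name, genes$biotype),
    sprintf("%s\tcardioreg_sim\texon\t%d\t%d\t.\t+\t.\tParent=%s",
            exons$chrom, exons$start + 1, exons$end, exons$gene))
  writeLines(c("##gff-version 3", gff), file.path(out_dir, "genes.gff3"))

  ## ---- planted enhancer SNPs -------------------------------------------
  mix <- params$category_mix
  n_planted <- sum(mix)
  category <- rep(names(mix), mix)
  k <- seq_len(n_planted)
  planted <- data.frame(
    rsid = sprintf("rsP%04d", k),
    chrom = "chr1",
    snp_start = 1000000 + (k - 1) * 3000 + flank,
    category = category, stringsAsFactors = FALSE)
  planted$win_start <- planted$snp_start - flank
  planted$win_end <- planted$snp_start + flank
  stage_sets <- lapply(planted$category, function(cat) {
    if (cat == "always_active") return(CARNEGIE_STAGES)
    groups <- strsplit(cat, "_")[[1]]
    unlist(STAGE_GROUPS[groups], use.names = FALSE)
  })
  src_code <- (k - 1) %% 15
  planted$source <- ifelse(src_code < 10, "gwas",
                           ifelse(src_code < 13, "clinvar", "both"))

  ## ---- decoy and annotation-variety SNPs -------------------------------
  nn <- params$n_noise_snps
  noise <- data.frame(
    rsid = sprintf("rsN%03d", seq_len(nn)),
    chrom = "chr2",
    snp_start = 400000 + (seq_len(nn) - 1) * 5000 + flank,
    stringsAsFactors = FALSE)
  annot <- data.frame(
    rsid = sprintf("rsA%02d", 1:6),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2", "chr2"),
    snp_start = c(genes$start[1] + 2000, genes$start[4] + 2500,   # intronic
                  genes$start[1] - 500, genes$start[3] - 800,     # promoter (+ strand TSS)
                  nc$start[1] + 3000, nc$start[2] + 5000),        # ncRNA body
    stringsAsFactors = FALSE)
  coding <- data.frame(
    rsid = sprintf("rsC%02d", seq_len(cg)),
    chrom = "chr1",
    snp_start = genes$start[seq_len(cg)] + 200,                   # inside exon 1
    gene = genes$name[seq_len(cg)], stringsAsFactors = FALSE)

  ## ---- GWAS catalogue ---------------------------------------------------
  chd_traits <- c("Atrial septal defect", "Ventricular septal defect",
                  "Tetralogy of Fallot", "Congenital heart disease",
                  "Patent ductus arteriosus", "Hypoplastic left heart syndrome")
  gwas_planted <- planted[planted$source %in% c("gwas", "both"), , drop = FALSE]
  gwas_p <- 10^-stats::runif(nrow(gwas_planted), 6, 30)
  gwas <- data.frame(
    SNPS = gwas_planted$rsid,
    CHR_ID = sub("chr", "", gwas_planted$chrom),
    CHR_POS = gwas_planted$snp_start + 1,
    trait = chd_traits[(seq_len(nrow(gwas_planted)) - 1) %% length(chd_traits) + 1],
    `P-VALUE` = sprintf("%.3e", gwas_p),
    stringsAsFactors = FALSE, check.names = FALSE)
  add_gwas <- function(rsid, chrom, pos0, trait, p) {
    data.frame(SNPS = rsid, CHR_ID = sub("chr", "", chrom), CHR_POS = pos0 + 1,
               trait = trait, `P-VALUE` = p, stringsAsFactors = FALSE,
               check.names = FALSE)
  }
  gwas <- rbind(
    gwas,
    add_gwas(noise$rsid, noise$chrom, noise$snp_start,
             chd_traits[(seq_len(nn) - 1) %% length(chd_traits) + 1],
             sprintf("%.3e", 10^-stats::runif(nn, 6, 20))),
    add_gwas(annot$rsid, annot$chrom, annot$snp_start, "Congenital heart disease",
             sprintf("%.3e", 10^-stats::runif(6, 6, 12))),
    # non-CHD traits, strongly significant: must be dropped by the lexicon
    add_gwas(sprintf("rsD%03d", 1:20), "chr2", 800000 + (1:20) * 1000,
             "Body height", "1.000e-12"),
    # CHD traits at/above the significance threshold: near-miss fixtures
    add_gwas(sprintf("rsU%02d", 1:5), "chr2", 850000 + (1:5) * 1000,
             "Atrial septal defect",
             c("1.000e-05", "2.000e-05", "5.000e-05", "8.000e-05", "9.900e-05")),
    # CHD trait without a p-value: excluded with a warning
    add_gwas("rsNOP01", "chr2", 860000, "Ventricular septal defect", "")
  )
  names(gwas)[names(gwas) == "trait"] <- "DISEASE/TRAIT"
  write_tsv(gwas, file.path(out_dir, "gwas_catalog.tsv"))

  ## ---- ClinVar table ----------------------------------------------------
  cv_planted <- planted[planted$source %in% c("clinvar", "both"), , drop = FALSE]
  sigs <- c("Pathogenic", "Uncertain significance", "Likely pathogenic")
  stats_txt <- c("criteria provided, single submitter",
                 "criteria provided, multiple submitters, no conflicts",
                 "reviewed by expert panel")
  i <- seq_len(nrow(cv_planted))
  cv_row <- function(rsid, chrom, start0, end0, type, sig, status, trait) {
    data.frame(Name = paste0("VAR_", rsid), Type = type,
               ClinicalSignificance = sig, ReviewStatus = status,
               PhenotypeList = trait, Chromosome = sub("chr", "", chrom),
               Start = start0 + 1, Stop = end0, `RS#` = sub("^rs", "", rsid),
               stringsAsFactors = FALSE, check.names = FALSE)
  }
  clinvar <- rbind(
    cv_row(cv_planted$rsid, cv_planted$chrom, cv_planted$snp_start,
           cv_planted$snp_start + 1, "single nucleotide variant",
           sigs[(i - 1) %% 3 + 1], stats_txt[(i - 1) %% 3 + 1],
           chd_traits[(i - 1) %% length(chd_traits) + 1]),
    cv_row(coding$rsid, coding$chrom, coding$snp_start, coding$snp_start + 1,
           "single nucleotide variant", "Pathogenic",
           "criteria provided, multiple submitters, no conflicts",
           "Congenital heart disease"),
    # structural variants for the type tally
    cv_row(sprintf("rsSV%02d", 1:16), "chr2",
           900000 + (1:16) * 2000, 900000 + (1:16) * 2000 + c(rep(50, 5),
           rep(120, 4), rep(20, 3), rep(8, 2), rep(40, 2)),
           rep(c("Deletion", "Duplication", "Indel", "Insertion", "Microsatellite"),
               c(5, 4, 3, 2, 2)),
           "Uncertain significance", "criteria provided, single submitter",
           "Congenital heart disease")
  )
  # benign variants inside the last n_benign_excluded planted windows
  nbx <- params$n_benign_excluded
  bx_k <- (n_planted - nbx + 1):n_planted
  clinvar <- rbind(
    clinvar,
    cv_row(sprintf("rsB%03d", seq_len(nbx)), "chr1", planted$snp_start[bx_k] + 20,
           planted$snp_start[bx_k] + 21, "single nucleotide variant", "Benign",
           "criteria provided, multiple submitters, no conflicts", "not provided"),
    # near-miss: benign but only 1 star -> the window must be retained
    cv_row("rsB900", "chr1", planted$snp_start[n_planted - nbx] + 20,
           planted$snp_start[n_planted - nbx] + 21, "single nucleotide variant",
           "Benign", "criteria provided, single submitter", "not provided")
  )
  write_tsv(clinvar, file.path(out_dir, "clinvar_variants.tsv"))

  ## ---- peak tracks ------------------------------------------------------
  sig_lo <- params$planted_signal[1]; sig_hi <- params$planted_signal[2]
  bg_lo <- params$background_signal[1]; bg_hi <- params$background_signal[2]
  planted_marks <- c("H3K27ac", "H3K4me1")
  for (stage in CARNEGIE_STAGES) {
    for (mark in HISTONE_MARKS) {
      rows <- list()
      if (mark %in% planted_marks) {
        active <- which(vapply(stage_sets, function(s) stage %in% s, logical(1)))
        if (length(active)) {
          rows[[1]] <- data.frame(
            chrom = "chr1",
            start = planted$win_start[active] - 10,
            end = planted$win_end[active] + 10,
            pval = stats::runif(length(active), sig_lo, sig_hi))
        }
      }
      nb <- params$background_peaks_per_track
      bg_chrom <- sample(names(genome), nb, replace = TRUE)
      bg_start <- floor(stats::runif(nb) * (genome[bg_chrom] - 300))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = bg_chrom, start = bg_start, end = bg_start + 300,
        pval = stats::runif(nb, bg_lo, bg_hi))
      if (stage == "CS13" && mark == "H3K27ac") {
        # near-miss: signal 8.9 under the first decoy window
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = noise$chrom[1], start = noise$snp_start[1] - flank - 10,
          end = noise$snp_start[1] + flank + 10, pval = 8.9)
      }
      pk <- do.call(rbind, rows)
      pk <- pk[order(pk$chrom, pk$start), , drop = FALSE]
      lines <- sprintf("%s\t%d\t%d\t%s\t0\t.\t%.4f\t%.4f\t-1\t75",
                       pk$chrom, as.integer(pk$start), as.integer(pk$end),
                       sprintf("%s_%s_pk%04d", stage, mark, seq_len(nrow(pk))),
                       pk$pval, pk$pval)
      writeLines(lines, file.path(out_dir, "peaks",
                                  paste0(stage, "_", mark, ".narrowPeak")))
    }
  }

  ## ---- conservation tracks ---------------------------------------------
  be <- beta_shape(params$cons_enh["mean"], params$cons_enh["sd"])
  bb <- beta_shape(params$cons_bg["mean"], params$cons_bg["sd"])
  planted$cons_mean <- stats::rbeta(n_planted, be["a"], be["b"])
  cons_lines <- character(0)
  for (chrom in names(genome)) {
    size <- genome[[chrom]]
    wins <- planted[planted$chrom == chrom, , drop = FALSE]
    wins <- wins[order(wins$win_start), , drop = FALSE]
    bounds <- rbind(cbind(wins$win_start, wins$win_end, wins$cons_mean))
    segs <- list()
    cursor <- 0
    add_tiles <- function(from, to) {
      if (to <= from) return(NULL)
      starts <- seq(from, to - 1, by = 150)
      ends <- pmin(starts + 150, to)
      data.frame(start = starts, end = ends,
                 val = stats::rbeta(length(starts), bb["a"], bb["b"]))
    }
    if (nrow(wins)) {
      for (w in seq_len(nrow(wins))) {
        segs[[length(segs) + 1L]] <- add_tiles(cursor, wins$win_start[w])
        segs[[length(segs) + 1L]] <- data.frame(start = wins$win_start[w],
                                                end = wins$win_end[w],
                                                val = wins$cons_mean[w])
        cursor <- wins$win_end[w]
      }
    }
    segs[[length(segs) + 1L]] <- add_tiles(cursor, size)
    seg <- do.call(rbind, segs)
    cons_lines <- c(cons_lines,
                    sprintf("%s\t%d\t%d\t%.6f", chrom, as.integer(seg$start),
                            as.integer(seg$end), seg$val))
  }
  writeLines(cons_lines, file.path(out_dir, "phastcons.bedGraph"))

  npc <- params$n_phylop_conserved
  all_nc_snps <- rbind(planted[, c("rsid", "chrom", "snp_start")],
                       noise[, c("rsid", "chrom", "snp_start")],
                       annot[, c("rsid", "chrom", "snp_start")])
  phylop <- stats::runif(nrow(all_nc_snps), -2, 5.8)
  phylop[seq_len(npc)] <- stats::runif(npc, 6, 10)   # first npc planted SNPs
  near_miss_phylop_rsid <- noise$rsid[2]
  phylop[all_nc_snps$rsid == near_miss_phylop_rsid] <- 5.9
  o <- order(all_nc_snps$chrom, all_nc_snps$snp_start)
  writeLines(sprintf("%s\t%d\t%d\t%.4f", all_nc_snps$chrom[o],
                     as.integer(all_nc_snps$snp_start[o]),
                     as.integer(all_nc_snps$snp_start[o] + 1), phylop[o]),
             file.path(out_dir, "phylop.bedGraph"))

  ## ---- eQTL tables ------------------------------------------------------
  step <- round(1 / params$eqtl_fraction)
  rk <- k[k %% step == 0]
  eq <- data.frame(
    rsid = planted$rsid[rk], chrom = planted$chrom[rk],
    pos = planted$snp_start[rk],
    tissue = CARDIAC_TISSUES[(rk / step - 1) %% 4 + 1],
    gene = sprintf("GENE%02d", (rk %% cg) + 1), stringsAsFactors = FALSE)
  multi <- rk[rk %% (5 * step) == 0]
  if (length(multi)) {
    second <- data.frame(
      rsid = planted$rsid[multi], chrom = planted$chrom[multi],
      pos = planted$snp_start[multi],
      tissue = CARDIAC_TISSUES[(multi / step) %% 4 + 1],
      gene = sprintf("GENE%02d", (multi %% cg) + 1), stringsAsFactors = FALSE)
    eq <- rbind(eq, second)
  }
  decoy_eq <- data.frame(
    rsid = sprintf("rsE%02d", 1:10), chrom = "chr2", pos = 950000 + (1:10) * 137,
    tissue = CARDIAC_TISSUES[(0:9) %% 4 + 1],
    gene = sprintf("GENE%02d", (0:9) %% cg + 1), stringsAsFactors = FALSE)
  eq_all <- rbind(eq, decoy_eq)
  for (tissue in CARDIAC_TISSUES) {
    sub <- eq_all[eq_all$tissue == tissue, , drop = FALSE]
    df <- data.frame(variant_id = sprintf("%s_%d_A_G_b38", sub$chrom, sub$pos + 1),
                     gene_id = sub$gene, stringsAsFactors = FALSE)
    write_tsv(df, file.path(out_dir, "eqtl", paste0(tissue, ".tsv")))
  }

  ## ---- motifs and sequences --------------------------------------------
  ms <- gen_motif_set(seed = NULL, n_seqs = params$n_motif_seqs,
                      seq_len = params$motif_seq_len,
                      n_decoys = params$n_decoy_motifs)
  write_jaspar_pfm(ms$pfms, file.path(out_dir, "motifs.jaspar"))
  writeLines(as.vector(rbind(paste0(">", names(ms$sequences)), ms$sequences)),
             file.path(out_dir, "enhancer_seqs.fasta"))

  ## ---- interaction network ---------------------------------------------
  pg <- gen_planted_graph(seed = NULL, sizes = params$clique_sizes,
                          p_in = params$p_in, p_out = params$p_out,
                          node_names = genes$name[seq_len(sum(params$clique_sizes))])
  ext <- data.frame(geneA = c("EXT1", "EXT2", "EXT3"),
                    geneB = c(pg$edges$geneA[1], pg$edges$geneA[1],
                              pg$edges$geneB[1]),
                    interaction_type = "physical", stringsAsFactors = FALSE)
  decoy_edges <- data.frame(geneA = genes$name[1:3], geneB = genes$name[11:13],
                            interaction_type = "genetic", stringsAsFactors = FALSE)
  write_tsv(rbind(pg$edges, ext, decoy_edges), file.path(out_dir, "ppi_edges.tsv"))

  ## ---- structure inputs -------------------------------------------------
  write_pdb(toy_complex_atoms(), file.path(out_dir, "complex.pdb"))
  ddg <- data.frame(
    chain1 = "A", chain2 = "B",
    mutated_chain = c(rep("B", 6), "A", "A"),
    mutation = c("R1H", "K2R", "E3Q", "G4S", "A5V", "N6S", "L7M", "F8S"),
    ddg = c(1.8, 0.44, 0.03, 1.35, -0.02, 1.49, -1.2, 0.9),
    stringsAsFactors = FALSE)
  write_tsv(ddg, file.path(out_dir, "ddg_synthetic.tsv"))

  ## ---- genome bookkeeping ----------------------------------------------
  write_tsv(data.frame(chrom = names(genome), size = unname(genome)),
            file.path(out_dir, "genome.sizes"))
  gaps <- data.frame(chrom = c("chr1", "chr2"),
                     start = c(0, genome[["chr2"]] - 10000),
                     end = c(10000, genome[["chr2"]]))
  coding_exons <- exons[exons$gene %in% genes$name[genes$biotype == "coding"], ,
                        drop = FALSE]
  excl <- rbind(coding_exons[, c("chrom", "start", "end")],
                gaps[, c("chrom", "start", "end")])
  excl <- excl[order(excl$chrom, excl$start), , drop = FALSE]
  writeLines(sprintf("%s\t%d\t%d", excl$chrom, as.integer(excl$start),
                     as.integer(excl$end)),
             file.path(out_dir, "exclusion.bed"))

  ## ---- manifest ---------------------------------------------------------
  planted$cons_class <- classify_conservation(planted$cons_mean)
  planted$benign_excluded <- k %in% bx_k
  manifest <- list(
    seed = seed,
    params = params,
    planted_enhancers = planted[, c("rsid", "chrom", "win_start", "win_end",
                                    "snp_start", "category", "source",
                                    "cons_mean", "cons_class", "benign_excluded")],
    noise_snps = noise,
    annotation_snps = annot,
    coding_snps = coding,
    phylop_conserved_rsids = planted$rsid[seq_len(npc)],
    eqtl_truth = eq,
    n_rchd_snps = length(unique(eq$rsid)),
    motif = list(planted_id = ms$planted_id, truth = ms$truth),
    network = list(membership = as.list(pg$membership),
                   added_nodes = ext$geneA),
    ddg_deleterious = ddg$mutation[abs(ddg$ddg) >= 1.5],
    near_misses = list(peak_signal_8.9_rsid = noise$rsid[1],
                       gwas_p_at_threshold = "rsU01",
                       benign_one_star_rsid = "rsB900",
                       phylop_5.9_rsid = near_miss_phylop_rsid)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
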