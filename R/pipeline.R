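#' Assemble a pipeline configuration
#'
#' Collects input paths (defaulting to the layout written by
#' [generate_scenario()]) and every analysis threshold. Paths are validated
#' up front so a misconfigured run fails before any compute.
#'
#' @param scenario_dir directory holding the inputs.
#' @param p_threshold GWAS significance cutoff (exclusive).
#' @param pval_signal peak-confidence threshold (inclusive).
#' @param flank window flank in bp.
#' @param mark_rule histone-mark rule for stage activity.
#' @param min_stages optional minimum active-stage pre-filter.
#' @param phastcons_conserved,phastcons_ultra element conservation cutoffs.
#' @param phylop_min per-base SNP conservation cutoff.
#' @param n_background background intervals for the conservation contrast.
#' @param motif_p per-hit scan p-value cutoff.
#' @param motif_q motif significance cutoff.
#' @param ddg_threshold deleteriousness cutoff (kcal/mol).
#' @param inflation MCL inflation.
#' @param seed seed for the background sampler.
#' @return config list.
#' @export
pipeline_config <- function(scenario_dir,
                            p_threshold = 1e-5, pval_signal = 9.0,
                            flank = 75L, mark_rule = "any", min_stages = NULL,
                            phastcons_conserved = 0.6, phastcons_ultra = 0.8,
                            phylop_min = 6.0, n_background = 10000L,
                            motif_p = 1e-4, motif_q = 0.05,
                            ddg_threshold = 1.5, inflation = 2.0, seed = 1L) {
  paths <- list(
    gwas = file.path(scenario_dir, "gwas_catalog.tsv"),
    clinvar = file.path(scenario_dir, "clinvar_variants.tsv"),
    genes = file.path(scenario_dir, "genes.gff3"),
    peaks = file.path(scenario_dir, "peaks"),
    phastcons = file.path(scenario_dir, "phastcons.bedGraph"),
    phylop = file.path(scenario_dir, "phylop.bedGraph"),
    eqtl_dir = file.path(scenario_dir, "eqtl"),
    motifs = file.path(scenario_dir, "motifs.jaspar"),
    fasta = file.path(scenario_dir, "enhancer_seqs.fasta"),
    edges = file.path(scenario_dir, "ppi_edges.tsv"),
    pdb = file.path(scenario_dir, "complex.pdb"),
    ddg = file.path(scenario_dir, "ddg_synthetic.tsv"),
    genome_sizes = file.path(scenario_dir, "genome.sizes"),
    exclusion = file.path(scenario_dir, "exclusion.bed")
  )
  missing <- !vapply(paths, file.exists, logical(1))
  if (any(missing)) {
    stop("missing pipeline input(s): ",
         paste(unlist(paths[missing]), collapse = ", "), call. = FALSE)
  }
  stopifnot(p_threshold > 0, pval_signal > 0, flank >= 0, phylop_min > 0,
            ddg_threshold > 0, inflation > 0, n_background > 0)
  c(list(paths = paths), as.list(environment())[setdiff(
    names(formals(pipeline_config)), "scenario_dir")])
}

#' Run both pipeline branches end to end
#'
#' Executes catalogue filtering, region annotation and the coding/noncoding
#' split; the noncoding branch (windows, enhancer calling, stage
#' categories, benign exclusion, conservation contrast, phyloP SNP filter,
#' eQTL designation, motif scan); and the coding branch (network assembly,
#' MCL clustering, ddG classification, interface detection). Returns a
#' report of every stage's counts; when `out_dir` is given, per-stage
#' tables, a JSON report and a markdown summary are written there.
#'
#' @param config list from [pipeline_config()].
#' @param out_dir optional output directory for stage files.
#' @return report list (invisibly when `out_dir` is given).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  paths <- config$paths
  report <- list(parameters = config[setdiff(names(config), "paths")])

  ## catalogue filtering ---------------------------------------------------
  gwas <- read_gwas_catalog(paths$gwas)
  clinvar_all <- read_clinvar(paths$clinvar)
  chd <- suppressWarnings(
    filter_chd(rbind(gwas, clinvar_all), p_threshold = config$p_threshold))
  report$snp_catalog <- list(
    n_gwas_input = nrow(gwas), n_clinvar_input = nrow(clinvar_all),
    n_chd = nrow(chd),
    n_chd_by_source = as.list(table(chd$source)),
    variant_types = as.list(classify_variant_types(chd)))

  ## region annotation -----------------------------------------------------
  model <- read_gene_model(paths$genes)
  chd <- suppressWarnings(classify_location(chd, model))
  dist <- category_distribution(chd)
  report$region_annotation <- list(distribution = dist)
  parts <- split_coding_noncoding(chd)
  report$split <- list(n_coding = nrow(parts$coding),
                       n_noncoding = nrow(parts$noncoding))

  ## noncoding branch ------------------------------------------------------
  sizes_df <- utils::read.table(paths$genome_sizes, header = TRUE, sep = "\t")
  chrom_sizes <- stats::setNames(sizes_df$size, sizes_df$chrom)
  nc_snps <- parts$noncoding[parts$noncoding$variant_type == "snp", , drop = FALSE]
  windows <- expand_windows(nc_snps, flank = config$flank,
                            chrom_sizes = chrom_sizes)
  peaks <- read_peak_dir(paths$peaks)
  activity <- stage_activity(windows, peaks, threshold = config$pval_signal)
  calls <- call_enhancers(windows, activity, mark_rule = config$mark_rule)
  calls <- classify_stage_category(calls, min_stages = config$min_stages)
  calls_kept <- exclude_benign(calls, clinvar_all)
  report$enhancers <- list(
    n_windows = nrow(windows),
    n_calls = nrow(calls),
    n_after_benign_exclusion = nrow(calls_kept),
    by_provenance = as.list(table(calls$provenance)),
    per_stage = as.list(stats::setNames(vapply(CARNEGIE_STAGES, function(s) {
      sum(vapply(strsplit(calls$active_stages, ","), function(x) s %in% x,
                 logical(1)))
    }, numeric(1)), CARNEGIE_STAGES)),
    stage_categories = as.list(table(calls$stage_category)))

  # conservation, eQTL and motif analyses run on the full merged call set;
  # the benign-screened subset is a separate deliverable
  phast <- suppressWarnings(read_track(paths$phastcons))
  enh_cons <- mean_conservation(calls[, c("chrom", "start", "end")], phast)
  excl <- read_bed(paths$exclusion)
  bg <- sample_background(chrom_sizes, excl, n = config$n_background,
                          seed = config$seed)
  bg_cons <- mean_conservation(bg[, c("chrom", "start", "end")], phast)
  wt <- rank_sum_test(enh_cons$mean_score, bg_cons$mean_score)
  cons_class <- classify_conservation(enh_cons$mean_score)
  phylop <- suppressWarnings(read_track(paths$phylop))
  conserved_snps <- suppressWarnings(
    filter_conserved_snps(nc_snps, phylop, min_score = config$phylop_min))
  report$conservation <- list(
    enh_mean = mean(enh_cons$mean_score), enh_sd = stats::sd(enh_cons$mean_score),
    bg_mean = mean(bg_cons$mean_score), bg_sd = stats::sd(bg_cons$mean_score),
    wilcoxon_p = wt$p_value,
    n_conserved = sum(cons_class != "none"),
    n_ultra = sum(cons_class == "ultra"),
    n_phylop_conserved_snps = nrow(conserved_snps))

  eqtls <- do.call(rbind, lapply(CARDIAC_TISSUES, function(t) {
    f <- file.path(paths$eqtl_dir, paste0(t, ".tsv"))
    if (file.exists(f)) read_eqtl_table(f, t) else NULL
  }))
  rchd <- match_eqtls(calls, eqtls)
  report$eqtl <- list(n_rchd_snps = rchd$n_rchd_snps,
                      per_tissue = as.list(rchd$per_tissue))

  sequences <- read_fasta(paths$fasta)
  pfms <- read_jaspar_pfm(paths$motifs)
  base_freq <- sequence_background(sequences)
  pwms <- lapply(names(pfms), function(id) {
    build_pwm(pfms[[id]], background = base_freq, motif_id = id,
              name = attr(pfms[[id]], "name"))
  })
  hits <- scan_motifs(sequences, pwms, p_threshold = config$motif_p)
  msig <- motif_significance(hits, q_threshold = config$motif_q)
  report$motifs <- list(
    n_hits = nrow(hits),
    n_significant_motifs = length(unique(msig$motif_id[msig$significant])),
    top_motif = if (nrow(msig)) msig$motif_id[1] else NA_character_)

  ## coding branch ---------------------------------------------------------
  coding_exons <- model$exons[model$exons$gene %in%
                                model$genes$name[model$genes$biotype == "coding"], ]
  ov <- interval_overlaps(parts$coding, coding_exons)
  query_genes <- sort(unique(coding_exons$gene[ov$b_idx]))
  edge_table <- utils::read.table(paths$edges, header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE)
  network <- build_network(query_genes, edge_table)
  clustering <- mcl(network, inflation = config$inflation)
  summ <- cluster_summary(clustering, network)
  report$ppin <- list(
    n_nodes = nrow(network$nodes), n_edges = nrow(network$edges),
    n_added = sum(network$nodes$origin == "added"),
    n_clusters = clustering$n_clusters,
    largest = as.list(summ$clusters[1, ]),
    smallest = as.list(summ$clusters[nrow(summ$clusters), ]))

  muts <- read_mutation_table(paths$ddg)
  ranked <- rank_mutations(muts, threshold = config$ddg_threshold)
  atoms <- read_pdb_atoms(paths$pdb)
  iface <- detect_interface(atoms, ranked$chain1[1], ranked$chain2[1])
  top <- ranked[1, ]
  contacts_top <- tryCatch(
    count_contacts(atoms, top$mutated_chain, top$position),
    error = function(e) NA_integer_)
  report$structure <- list(
    n_mutations = nrow(ranked),
    max_ddg = attr(ranked, "summary")$max_ddg,
    n_deleterious = attr(ranked, "summary")$n_deleterious,
    top_mutation = top$mutation,
    n_interface_residues = sum(iface$interface),
    n_surface_residues = sum(!iface$interface),
    top_mutation_contacts = contacts_top)

  ## consistency and outputs ----------------------------------------------
  stopifnot(report$split$n_coding + report$split$n_noncoding == nrow(chd),
            report$enhancers$n_calls <= report$enhancers$n_windows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_bed(data.frame(chrom = calls_kept$chrom, start = calls_kept$start,
                         end = calls_kept$end, name = calls_kept$rsid,
                         score = calls_kept$max_signal, strand = "."),
              file.path(out_dir, "enhancer_calls.bed"))
    write_tsv(calls_kept, file.path(out_dir, "enhancer_calls.tsv"))
    write_tsv(enh_cons, file.path(out_dir, "enhancer_conservation.tsv"))
    write_tsv(rchd$matches, file.path(out_dir, "rchd_snps.tsv"))
    write_tsv(msig, file.path(out_dir, "motif_significance.tsv"))
    write_tsv(data.frame(gene = names(clustering$partition),
                         cluster = unname(clustering$partition)),
              file.path(out_dir, "clusters.tsv"))
    write_tsv(ranked, file.path(out_dir, "mutations_ranked.tsv"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(render_report_md(report), file.path(out_dir, "report.md"))
    return(invisible(report))
  }
  report
}

# 0-order base composition of a sequence set (A,C,G,T frequencies).
sequence_background <- function(sequences) {
  tab <- table(factor(strsplit(paste(sequences, collapse = ""), "")[[1]],
                      levels = c("A", "C", "G", "T")))
  f <- as.numeric(tab)
  if (sum(f) == 0) return(rep(0.25, 4))
  f / sum(f)
}

render_report_md <- function(report) {
  c("# CHD-SNP pipeline report", "",
    sprintf("- CHD variants retained: %d (GWAS %s / ClinVar %s)",
            report$snp_catalog$n_chd,
            report$snp_catalog$n_chd_by_source[["gwas"]],
            report$snp_catalog$n_chd_by_source[["clinvar"]]),
    sprintf("- Coding / noncoding split: %d / %d",
            report$split$n_coding, report$split$n_noncoding),
    sprintf("- Enhancer calls: %d (%d after benign exclusion)",
            report$enhancers$n_calls, report$enhancers$n_after_benign_exclusion),
    sprintf("- Conservation: enhancer mean %.4f vs background %.4f (Wilcoxon p = %.3g)",
            report$conservation$enh_mean, report$conservation$bg_mean,
            report$conservation$wilcoxon_p),
    sprintf("- Conserved / ultra-conserved elements: %d / %d",
            report$conservation$n_conserved, report$conservation$n_ultra),
    sprintf("- phyloP-conserved SNPs: %d",
            report$conservation$n_phylop_conserved_snps),
    sprintf("- rCHD-SNPs: %d", report$eqtl$n_rchd_snps),
    sprintf("- Significant motifs: %d (top: %s)",
            report$motifs$n_significant_motifs, report$motifs$top_motif),
    sprintf("- Network: %d nodes, %d edges, %d clusters",
            report$ppin$n_nodes, report$ppin$n_edges, report$ppin$n_clusters),
    sprintf("- Mutations: %d, deleterious %d (top: %s, ddG %.2f)",
            report$structure$n_mutations, report$structure$n_deleterious,
            report$structure$top_mutation, report$structure$max_ddg))
}
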