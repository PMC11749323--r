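# One shared synthetic scenario (seed 17) and derived objects, generated
# once per test run.
.scn <- new.env(parent = emptyenv())

scenario_dir <- function() {
  if (is.null(.scn$dir)) {
    dir <- file.path(tempdir(), "cardioreg_scn17")
    .scn$manifest <- generate_scenario(dir, seed = 17)
    .scn$dir <- dir
  }
  .scn$dir
}

scenario_manifest <- function() {
  scenario_dir()
  .scn$manifest
}

# Enhancer calls recomputed from the scenario's raw files (full merged set,
# before the benign screen).
scenario_calls <- function() {
  if (is.null(.scn$calls)) {
    dir <- scenario_dir()
    gwas <- read_gwas_catalog(file.path(dir, "gwas_catalog.tsv"))
    clinvar <- read_clinvar(file.path(dir, "clinvar_variants.tsv"))
    chd <- suppressWarnings(filter_chd(rbind(gwas, clinvar)))
    model <- read_gene_model(file.path(dir, "genes.gff3"))
    chd <- suppressWarnings(classify_location(chd, model))
    nc <- split_coding_noncoding(chd)$noncoding
    nc <- nc[nc$variant_type == "snp", , drop = FALSE]
    windows <- expand_windows(nc)
    peaks <- read_peak_dir(file.path(dir, "peaks"))
    activity <- stage_activity(windows, peaks)
    .scn$windows <- windows
    .scn$calls <- classify_stage_category(call_enhancers(windows, activity))
  }
  .scn$calls
}

scenario_report <- function() {
  if (is.null(.scn$report)) {
    cfg <- pipeline_config(scenario_dir(), seed = 1)
    .scn$report <- suppressWarnings(run_pipeline(cfg))
  }
  .scn$report
}
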