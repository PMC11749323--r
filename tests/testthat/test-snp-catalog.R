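make_records <- function(rsid, trait, p = NA, source = "gwas",
                         start = seq_along(rsid) * 100) {
  data.frame(rsid = rsid, chrom = "chr1", start = start, end = start + 1,
             source = source, traits = trait, p_value = p,
             variant_type = "snp", clinical_significance = NA_character_,
             review_stars = NA_integer_, stringsAsFactors = FALSE)
}

test_that("CHD filtering applies trait and significance rules", {
  recs <- make_records(c("rs1", "rs2", "rs3"),
                       c("Atrial septal defect", "Body height",
                         "Atrial septal defect"),
                       p = c(2e-9, 1e-12, 2e-5))
  out <- filter_chd(recs, p_threshold = 1e-5)
  expect_equal(out$rsid, "rs1")   # trait match AND p below threshold
  expect_equal(nrow(filter_chd(recs[0, , drop = FALSE])), 0L)
})

test_that("ClinVar records are retained on the trait match alone", {
  recs <- make_records("rs9", "Tetralogy of Fallot", p = NA, source = "clinvar")
  expect_equal(nrow(filter_chd(recs)), 1L)
})

test_that("GWAS records without a p-value are excluded with a warning", {
  recs <- make_records(c("rs1", "rs2"), "Atrial septal defect", p = c(NA, 1e-9))
  expect_warning(out <- filter_chd(recs), "without a p-value")
  expect_equal(out$rsid, "rs2")
})

test_that("filtering matches an independent two-predicate scan", {
  set.seed(11)
  traits <- sample(c("Atrial septal defect", "ventricular septal defect and stuff",
                     "Body height", "Type 2 diabetes", "Congenital heart disease"),
                   10, replace = TRUE)
  p <- 10^-runif(10, 3, 12)
  src <- sample(c("gwas", "clinvar"), 10, replace = TRUE)
  recs <- make_records(sprintf("rs%02d", 1:10), traits, p = p, source = src)
  lex <- chd_trait_lexicon()
  keep_oracle <- vapply(seq_len(10), function(i) {
    hit <- any(vapply(lex, function(t) grepl(t, tolower(traits[i]), fixed = TRUE),
                      logical(1)))
    hit && (src[i] == "clinvar" || p[i] < 1e-5)
  }, logical(1))
  out <- filter_chd(recs, p_threshold = 1e-5)
  expect_setequal(out$rsid, recs$rsid[keep_oracle])
})

test_that("filtering is idempotent and deduplicates by smallest p-value", {
  recs <- rbind(make_records(c("rs1", "rs1"), "Atrial septal defect",
                             p = c(1e-8, 1e-12), start = c(100, 100)),
                make_records("rs2", "Congenital heart disease", p = 1e-9,
                             start = 300))
  out <- filter_chd(recs)
  expect_equal(nrow(out), 2L)
  expect_equal(out$p_value[out$rsid == "rs1"], 1e-12)
  expect_identical(filter_chd(out), out)
})

test_that("variant type tallies match a hand count and flag unknown types", {
  set.seed(5)
  types <- sample(c("snp", "deletion", "duplication", "indel", "insertion",
                    "microsatellite"), 50, replace = TRUE)
  recs <- data.frame(variant_type = types, stringsAsFactors = FALSE)
  counts <- classify_variant_types(recs)
  for (t in unique(types)) expect_equal(unname(counts[t]), sum(types == t))
  expect_equal(sum(counts), 50L)
  expect_equal(unname(classify_variant_types(recs[0, , drop = FALSE])),
               rep(0L, 7))
  expect_warning(c2 <- classify_variant_types(
    data.frame(variant_type = "inversion")), "other")
  expect_equal(unname(c2["other"]), 1L)
})

test_that("coding/noncoding split is an exhaustive disjoint partition", {
  cats <- c("exonic", "intronic", "promoter", "distal_intergenic",
            "ncrna_intronic")
  set.seed(2)
  df <- data.frame(rsid = sprintf("rs%02d", 1:20),
                   region_category = sample(cats, 20, replace = TRUE),
                   stringsAsFactors = FALSE)
  parts <- split_coding_noncoding(df)
  expect_equal(nrow(parts$coding) + nrow(parts$noncoding), 20L)
  expect_equal(nrow(parts$coding), sum(df$region_category == "exonic"))
  expect_length(intersect(parts$coding$rsid, parts$noncoding$rsid), 0L)

  all_prom <- data.frame(region_category = rep("promoter", 3))
  parts2 <- split_coding_noncoding(all_prom)
  expect_equal(nrow(parts2$coding), 0L)
  expect_equal(nrow(parts2$noncoding), 3L)

  expect_error(split_coding_noncoding(data.frame(x = 1)), "region_category")
  expect_error(split_coding_noncoding(data.frame(region_category = NA)),
               "uncategorised")
})

test_that("catalogue readers convert 1-based positions and map review stars", {
  d <- scenario_dir()
  gw <- read_gwas_catalog(file.path(d, "gwas_catalog.tsv"))
  expect_true(all(gw$end - gw$start == 1))
  expect_true(all(grepl("^chr", gw$chrom)))
  cv <- read_clinvar(file.path(d, "clinvar_variants.tsv"))
  expect_true(all(cv$review_stars %in% 0:4))
  expect_true(any(cv$variant_type == "deletion"))
  # 1-based round trip: the manifest records 0-based SNP positions
  man <- scenario_manifest()
  one <- man$planted_enhancers[1, ]
  expect_true(any(gw$rsid == one$rsid & gw$start == one$snp_start))
})
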