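snp_df <- function(start, chrom = "chr1", rsid = "rs1", source = "gwas") {
  data.frame(chrom = chrom, start = start, end = start + 1, rsid = rsid,
             source = source, variant_type = "snp", stringsAsFactors = FALSE)
}

peak_df <- function(start, end, pval, stage = "CS13", mark = "H3K27ac",
                    chrom = "chr1") {
  data.frame(chrom = chrom, start = start, end = end, name = "p",
              mark = mark, stage = stage, pval_signal = pval,
              stringsAsFactors = FALSE)
}

test_that("window expansion reproduces the reference enhancer coordinates", {
  w <- expand_windows(snp_df(236688982))
  expect_equal(w$start, 236688907)
  expect_equal(w$end, 236689057)
  expect_equal(w$end - w$start, 150)
  expect_false(w$truncated)
  # the focal base stays inside the window for any positive flank
  for (flank in c(1, 10, 75, 400)) {
    wf <- expand_windows(snp_df(236688982), flank = flank)
    expect_true(wf$start <= 236688982 && wf$end >= 236688983)
  }
})

test_that("degenerate and clipped windows are flagged", {
  w0 <- expand_windows(snp_df(50), flank = 0)
  expect_equal(c(w0$start, w0$end), c(50, 51))
  expect_true(w0$degenerate)
  wc <- expand_windows(snp_df(10), flank = 75)
  expect_equal(c(wc$start, wc$end), c(0, 85))
  expect_true(wc$truncated)
  wr <- expand_windows(snp_df(990), flank = 75, chrom_sizes = c(chr1 = 1000))
  expect_equal(wr$end, 1000)
  expect_true(wr$truncated)
  non_snp <- snp_df(100); non_snp$end <- 105; non_snp$variant_type <- "deletion"
  expect_error(expand_windows(non_snp), "single-base")
})

test_that("stage activity applies the inclusive signal threshold per cell", {
  w <- expand_windows(snp_df(1000))
  act_hi <- stage_activity(w, peak_df(900, 1100, 9.5))
  expect_true(act_hi$active[act_hi$stage == "CS13" & act_hi$mark == "H3K27ac"])
  act_edge <- stage_activity(w, peak_df(900, 1100, 9.0))
  expect_true(act_edge$active[act_edge$stage == "CS13" & act_edge$mark == "H3K27ac"])
  act_lo <- stage_activity(w, peak_df(900, 1100, 8.9))
  expect_false(any(act_lo$active))
  expect_equal(act_lo$best_signal[act_lo$stage == "CS13" &
                                    act_lo$mark == "H3K27ac"], 8.9)
})

test_that("activity equals a brute-force all-pairs overlap scan", {
  set.seed(23)
  snps <- do.call(rbind, lapply(1:8, function(i) {
    snp_df(sample(500:5000, 1), rsid = paste0("rs", i))
  }))
  w <- expand_windows(snps)
  peaks <- do.call(rbind, lapply(1:20, function(i) {
    s <- sample(300:5200, 1)
    peak_df(s, s + sample(50:400, 1), runif(1, 5, 14),
            stage = sample(CARNEGIE_STAGES, 1), mark = sample(HISTONE_MARKS, 1))
  }))
  act <- stage_activity(w, peaks, threshold = 9)
  for (i in seq_len(nrow(w))) {
    for (s in CARNEGIE_STAGES) for (mk in HISTONE_MARKS) {
      sel <- peaks$stage == s & peaks$mark == mk &
        pmin(w$end[i], peaks$end) - pmax(w$start[i], peaks$start) >= 1
      want <- if (any(sel)) max(peaks$pval_signal[sel]) else NA_real_
      got <- act$best_signal[act$window_idx == i & act$stage == s & act$mark == mk]
      expect_equal(got, want)
    }
  }
})

test_that("raising the threshold never activates more cells", {
  set.seed(31)
  snps <- do.call(rbind, lapply(1:6, function(i) {
    snp_df(sample(500:4000, 1), rsid = paste0("rs", i))
  }))
  w <- expand_windows(snps)
  peaks <- do.call(rbind, lapply(1:30, function(i) {
    s <- sample(300:4200, 1)
    peak_df(s, s + 200, runif(1, 6, 14), stage = sample(CARNEGIE_STAGES, 1),
            mark = sample(HISTONE_MARKS, 1))
  }))
  a9 <- stage_activity(w, peaks, threshold = 9)
  a12 <- stage_activity(w, peaks, threshold = 12)
  expect_true(all(a9$active | !a12$active))
  expect_lte(sum(a12$active), sum(a9$active))
})

test_that("calls require one active stage and identical intervals merge provenance", {
  snps <- rbind(snp_df(1000, rsid = "rs1", source = "gwas"),
                snp_df(1000, rsid = "rs1", source = "clinvar"),
                snp_df(5000, rsid = "rs2", source = "gwas"))
  w <- expand_windows(snps)
  peaks <- peak_df(900, 1100, 12)
  calls <- call_enhancers(w, stage_activity(w, peaks))
  expect_equal(nrow(calls), 1L)     # rs2 window inactive, rs1 windows merged
  expect_equal(calls$provenance, "clinvar,gwas")
  expect_equal(calls$active_stages, "CS13")
  expect_lte(nrow(calls), nrow(w))
})

test_that("the mark rule switches between disjunction and conjunction", {
  w <- expand_windows(snp_df(1000))
  peaks <- rbind(peak_df(900, 1100, 12, mark = "H3K27ac"),
                 peak_df(900, 1100, 12, mark = "H3K4me1"))
  act <- stage_activity(w, peaks)
  expect_equal(nrow(call_enhancers(w, act, mark_rule = "any")), 1L)
  expect_equal(nrow(call_enhancers(w, act, mark_rule = "all")), 0L)
  expect_equal(nrow(call_enhancers(w, act, mark_rule = "H3K4me1")), 1L)
  expect_equal(nrow(call_enhancers(w, act, mark_rule = "H3K4me3")), 0L)
})

test_that("stage categories follow the contained-group rule", {
  categorise <- function(stages) {
    calls <- data.frame(chrom = "chr1", start = 0, end = 150, rsid = "rs1",
                        snp_start = 75, provenance = "gwas",
                        active_stages = paste(stages, collapse = ","),
                        n_active_stages = length(stages),
                        max_signal = 12, stringsAsFactors = FALSE)
    classify_stage_category(calls)$stage_category
  }
  expect_equal(categorise(c("CS13", "CS14", "CS16")), "early")
  expect_equal(categorise(c("CS17", "CS18", "CS19")), "intermediate")
  expect_equal(categorise(c("CS20", "CS21", "CS23")), "late")
  expect_equal(categorise(CARNEGIE_STAGES), "always_active")
  expect_equal(categorise(c("CS13", "CS14", "CS16", "CS20", "CS21", "CS23")),
               "early_late")
  expect_equal(categorise(c("CS13", "CS14", "CS16", "CS17", "CS18", "CS19")),
               "early_intermediate")
  expect_equal(categorise(c("CS13", "CS17")), "unclassified")
  # optional pre-filter on the number of active stages
  calls <- data.frame(chrom = "chr1", start = 0, end = 150, rsid = "rs1",
                      snp_start = 75, provenance = "gwas",
                      active_stages = "CS13,CS14,CS16", n_active_stages = 3,
                      max_signal = 12, stringsAsFactors = FALSE)
  expect_equal(nrow(classify_stage_category(calls, min_stages = 5)), 0L)
})

test_that("benign exclusion needs both the benign class and two stars", {
  calls <- data.frame(chrom = "chr1", start = 1000, end = 1150, rsid = "rs1",
                      stringsAsFactors = FALSE)
  cv <- function(sig, stars, pos = 1050) {
    data.frame(chrom = "chr1", start = pos, end = pos + 1,
               clinical_significance = sig, review_stars = stars,
               stringsAsFactors = FALSE)
  }
  expect_equal(nrow(exclude_benign(calls, cv("Benign", 2))), 0L)
  expect_equal(nrow(exclude_benign(calls, cv("Benign", 1))), 1L)
  expect_equal(nrow(exclude_benign(calls, cv("Pathogenic", 4))), 1L)
  expect_equal(nrow(exclude_benign(calls, cv("Benign", 3, pos = 5000))), 1L)
  expect_equal(nrow(exclude_benign(calls, cv("Likely benign", 2))), 0L)
})

test_that("cross-referencing against a known set matches the all-pairs scan", {
  set.seed(41)
  calls <- data.frame(chrom = sample(c("chr1", "chr2"), 100, replace = TRUE),
                      start = sample(0:20000, 100))
  calls$end <- calls$start + 150
  known <- data.frame(chrom = sample(c("chr1", "chr2"), 100, replace = TRUE),
                      start = sample(0:20000, 100))
  known$end <- known$start + sample(50:500, 100, replace = TRUE)
  xr <- cross_reference(calls, known)
  want <- oracle_overlaps(calls, known)
  got <- xr$pairs[order(xr$pairs$call_idx, xr$pairs$known_idx), ]
  want <- want[order(want$a_idx, want$b_idx), ]
  expect_equal(unname(as.matrix(got)), unname(as.matrix(want)))
  expect_equal(xr$n_calls_overlapping, length(unique(want$a_idx)))
  expect_equal(cross_reference(calls, known[0, , drop = FALSE])$n_calls_overlapping, 0L)
})
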