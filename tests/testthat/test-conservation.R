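track_from_lines <- function(lines) {
  f <- withr::local_tempfile(.local_envir = parent.frame())
  writeLines(lines, f)
  read_track(f)
}

test_that("mean conservation counts uncovered bases as zero", {
  tr <- track_from_lines("chr1\t0\t150\t0.5")
  full <- mean_conservation(data.frame(chrom = "chr1", start = 0, end = 150), tr)
  expect_equal(full$mean_score, 0.5)
  expect_equal(full$covered_fraction, 1)

  half <- mean_conservation(data.frame(chrom = "chr1", start = 75, end = 225), tr)
  expect_equal(half$mean_score, 0.25)        # 75 bases at 0.5, 75 uncovered
  expect_equal(half$covered_fraction, 0.5)
  half_cov <- mean_conservation(data.frame(chrom = "chr1", start = 75, end = 225),
                                tr, covered_only = TRUE)
  expect_equal(half_cov$mean_score, 0.5)

  expect_warning(
    off <- mean_conservation(data.frame(chrom = "chr9", start = 0, end = 10), tr),
    "absent")
  expect_equal(off$mean_score, 0)
})

test_that("interval means equal a per-base brute-force average", {
  set.seed(19)
  pos <- sort(sample(0:400, 250))
  sc <- round(runif(length(pos)), 4)
  tr <- track_from_lines(sprintf("chr1\t%d\t%d\t%s", pos, pos + 1, sc))
  ivs <- data.frame(chrom = "chr1", start = c(0, 37, 150), end = c(50, 201, 400))
  out <- mean_conservation(ivs, tr)
  for (i in seq_len(nrow(ivs))) {
    bases <- ivs$start[i]:(ivs$end[i] - 1)
    per_base <- vapply(bases, function(b) {
      v <- sc[pos == b]
      if (length(v)) v else 0
    }, numeric(1))
    expect_equal(out$mean_score[i], mean(per_base))
  }
})

test_that("the mean is linear in the track scores", {
  set.seed(3)
  pos <- sort(sample(0:200, 120))
  sc <- runif(length(pos))
  tr1 <- track_from_lines(sprintf("chr1\t%d\t%d\t%.6f", pos, pos + 1, sc))
  tr3 <- track_from_lines(sprintf("chr1\t%d\t%d\t%.6f", pos, pos + 1, 3 * sc))
  iv <- data.frame(chrom = "chr1", start = 10, end = 190)
  expect_equal(mean_conservation(iv, tr3)$mean_score,
               3 * mean_conservation(iv, tr1)$mean_score, tolerance = 1e-6)
})

test_that("background sampling is seeded, sized and exclusion-aware", {
  sizes <- c(chr1 = 50000, chr2 = 30000)
  excl <- data.frame(chrom = "chr1", start = 10000, end = 20000)
  a <- sample_background(sizes, excl, n = 500, length = 150, seed = 7)
  b <- sample_background(sizes, excl, n = 500, length = 150, seed = 7)
  expect_identical(a, b)
  expect_equal(nrow(a), 500L)
  expect_true(all(a$end - a$start == 150))
  expect_equal(nrow(interval_overlaps(a, excl)), 0L)
  c2 <- sample_background(sizes, excl, n = 500, length = 150, seed = 8)
  expect_false(identical(a, c2))
  expect_error(
    sample_background(c(chr1 = 1000), data.frame(chrom = "chr1", start = 0,
                                                 end = 1000),
                      n = 10, length = 150, seed = 1, max_tries = 10),
    "exhausted")
})

test_that("background start positions are uniform over the eligible space", {
  sizes <- c(chr1 = 20000, chr2 = 20000)
  bg <- sample_background(sizes, NULL, n = 10000, length = 150, seed = 17)
  # chi-square uniformity of starts pooled over both chromosomes
  bins <- cut(bg$start, breaks = seq(0, 20000, by = 2000))
  p <- stats::chisq.test(table(bins))$p.value
  expect_gt(p, 0.01)
  # and an even split between equally sized chromosomes
  expect_gt(stats::chisq.test(table(bg$chrom))$p.value, 0.01)
})

test_that("rank-sum test matches exact enumeration for small no-tie samples", {
  expect_equal(rank_sum_test(1:4, 5:8)$p_value, 2 / 70, tolerance = 1e-12)
  expect_equal(rank_sum_test(c(2, 2, 2), c(2, 2, 2))$p_value, 1)
  set.seed(29)
  for (n in 2:6) {
    for (rep in 1:6) {
      x <- sample(1:100, 2 * n)   # distinct values, no ties
      a <- x[seq_len(n)]; b <- x[-seq_len(n)]
      expect_equal(rank_sum_test(a, b)$p_value, oracle_rank_sum_p(a, b),
                   tolerance = 1e-12,
                   label = sprintf("n=%d rep=%d", n, rep))
    }
  }
})

test_that("rank-sum test detects a planted location shift", {
  set.seed(13)
  enh <- pmin(1, pmax(0, rnorm(500, 0.9, 0.1)))
  bg <- pmin(1, pmax(0, rnorm(500, 0.1, 0.1)))
  expect_lt(rank_sum_test(enh, bg)$p_value, 1e-10)
})

test_that("conservation classes use inclusive boundaries and are monotone", {
  expect_equal(classify_conservation(c(0.59, 0.6, 0.61, 0.79, 0.8, 0.85)),
               c("none", "conserved", "conserved", "conserved", "ultra", "ultra"))
  grid <- seq(0, 1, by = 0.01)
  cls <- classify_conservation(grid)
  lvl <- c(none = 0, conserved = 1, ultra = 2)
  expect_true(all(diff(lvl[cls]) >= 0))
})

test_that("per-base phyloP filtering equals a lookup oracle with inclusive cutoff", {
  set.seed(37)
  pos <- sort(sample(0:500, 200))
  sc <- round(runif(length(pos), -3, 10), 3)
  tr <- track_from_lines(sprintf("chr1\t%d\t%d\t%s", pos, pos + 1, sc))
  vpos <- sample(0:500, 30)
  variants <- data.frame(chrom = "chr1", start = vpos, end = vpos + 1,
                         rsid = sprintf("rs%02d", 1:30), stringsAsFactors = FALSE)
  out <- suppressWarnings(filter_conserved_snps(variants, tr, min_score = 6))
  keep_oracle <- vapply(vpos, function(p) {
    v <- sc[pos == p]
    length(v) == 1 && v >= 6
  }, logical(1))
  expect_setequal(out$rsid, variants$rsid[keep_oracle])

  tr2 <- track_from_lines(c("chr1\t0\t1\t6.0", "chr1\t1\t2\t5.9"))
  v2 <- data.frame(chrom = "chr1", start = 0:1, end = 1:2,
                   rsid = c("hit", "miss"), stringsAsFactors = FALSE)
  expect_equal(filter_conserved_snps(v2, tr2)$rsid, "hit")
})
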