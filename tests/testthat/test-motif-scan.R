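test_that("uniform counts on a uniform background give zero log-odds", {
  counts <- matrix(5, 4, 6, dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm <- build_pwm(counts)
  expect_equal(max(abs(pwm$log_odds)), 0)
  expect_equal(score_pvalue(pwm, 0), 1)   # every sequence scores 0
})

test_that("a concentrated column scores its base up and the rest down", {
  counts <- matrix(c(10, 0, 0, 0), 4, 1,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm <- build_pwm(counts, pseudocount = 0.1)
  expect_gt(pwm$log_odds["A", 1], 0)
  expect_true(all(pwm$log_odds[c("C", "G", "T"), 1] < 0))
  expect_error(build_pwm(counts, background = c(0.5, 0.5, 0, 0)), "positive")
  expect_error(build_pwm(matrix(0, 4, 2)), "all-zero")
})

test_that("the expected per-column score under the background is non-positive", {
  set.seed(47)
  for (rep in 1:10) {
    counts <- matrix(rpois(4 * 5, 4) + ifelse(runif(20) < 0.3, 15, 0), 4, 5)
    rownames(counts) <- c("A", "C", "G", "T")
    bg <- as.numeric(rdirichlet1(c(4, 4, 4, 4)))
    pwm <- build_pwm(counts, background = bg)
    expected <- colSums(pwm$log_odds * pwm$background)
    expect_true(all(expected <= 1e-9))
  }
})

test_that("the score distribution sums to one and p-values are non-increasing", {
  set.seed(53)
  counts <- matrix(rpois(4 * 8, 3) + 1, 4, 8,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm <- build_pwm(counts)
  expect_equal(sum(pwm$dist), 1, tolerance = 1e-9)
  scores <- seq(sum(apply(pwm$int_scores, 2, min)),
                sum(apply(pwm$int_scores, 2, max)),
                length.out = 40) * pwm$grid
  p <- score_pvalue(pwm, scores)
  expect_true(all(diff(p) <= 1e-12))
  expect_true(all(p > 0 & p <= 1))
  # minimum achievable score has the whole distribution above it
  min_score <- sum(apply(pwm$int_scores, 2, min)) * pwm$grid
  expect_equal(score_pvalue(pwm, min_score), 1)
  expect_warning(score_pvalue(pwm, 1e6), "above the maximum")
})

test_that("p-values equal 4^L exhaustive enumeration for short motifs", {
  set.seed(59)
  backgrounds <- list(uniform = rep(0.25, 4), skewed = c(0.4, 0.1, 0.1, 0.4))
  for (bg_name in names(backgrounds)) {
    for (L in c(3, 5)) {
      counts <- matrix(rpois(4 * L, 3) + ifelse(runif(4 * L) < 0.25, 12, 0) + 1,
                       4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
      pwm <- build_pwm(counts, background = backgrounds[[bg_name]])
      test_scores <- (c(sum(apply(pwm$int_scores, 2, min)),
                        sum(apply(pwm$int_scores, 2, max)),
                        sum(pwm$int_scores[1, ]),
                        sum(diag(pwm$int_scores[rep(1:4, length.out = L),
                                                seq_len(L), drop = FALSE]))) *
                       pwm$grid)
      for (s in test_scores) {
        expect_equal(score_pvalue(pwm, s), oracle_pwm_pvalue(pwm, s),
                     tolerance = 1e-9,
                     label = sprintf("bg=%s L=%d s=%.3f", bg_name, L, s))
      }
    }
  }
})

test_that("halving the grid step changes p-values by less than 5% relative", {
  set.seed(61)
  counts <- matrix(rpois(4 * 8, 3) + ifelse(runif(32) < 0.3, 10, 0) + 1, 4, 8,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm1 <- build_pwm(counts, grid = 0.001)
  pwm2 <- build_pwm(counts, grid = 0.0005)
  for (q in c(0.3, 0.6, 0.9)) {
    s <- q * sum(apply(pwm1$log_odds, 2, max))
    p1 <- score_pvalue(pwm1, s)
    p2 <- score_pvalue(pwm2, s)
    expect_lt(abs(p1 - p2) / p1, 0.05)
  }
})

test_that("a planted consensus is recovered as the best hit at its offset", {
  ms <- gen_motif_set(seed = 101, n_seqs = 1)
  consensus <- paste(c("T", "G", "A", "C", "G", "T", "C", "A", "T", "G", "C", "A"),
                     collapse = "")
  set.seed(71)
  bg <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE), collapse = "")
  seq <- paste0(substr(bg, 1, 37), consensus, substr(bg, 38, 120))
  pwm <- build_pwm(ms$pfms[[1]], motif_id = "planted")
  hits <- scan_motifs(c(s1 = seq), list(pwm))
  best <- hits[hits$best, ]
  expect_equal(best$offset, 37)
  expect_equal(best$strand, "+")
})

test_that("all-N sequences yield no significant hits", {
  ms <- gen_motif_set(seed = 5, n_seqs = 1)
  pwm <- build_pwm(ms$pfms[[1]], motif_id = "planted")
  hits <- scan_motifs(c(nn = strrep("N", 100)), list(pwm))
  expect_equal(nrow(hits), 0L)
  # and sequences shorter than the motif produce no hits, no error
  expect_equal(nrow(scan_motifs(c(tiny = "ACGT"), list(pwm))), 0L)
})

test_that("palindromic motifs score identically on both strands", {
  counts <- matrix(1, 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  counts["A", 1] <- 10; counts["C", 2] <- 10   # consensus ACGT = its own revcomp
  counts["G", 3] <- 10; counts["T", 4] <- 10
  pwm <- build_pwm(counts, motif_id = "pal")
  set.seed(83)
  seq <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
  hits <- scan_motifs(stats::setNames(seq, "s"), list(pwm), p_threshold = 1)
  fwd <- hits[hits$strand == "+", ]
  rev <- hits[hits$strand == "-", ]
  expect_equal(max(fwd$score), max(rev$score))
})

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(bh_qvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_qvalues(0.037), 0.037)
  expect_equal(bh_qvalues(rep(0.02, 5)), rep(0.02, 5))
  p <- c(0.005, 0.009, 0.05, 0.2, 0.9)
  manual <- rev(cummin(rev(sort(p) * length(p) / seq_along(p))))[rank(p)]
  expect_equal(bh_qvalues(p), manual)
  expect_error(bh_qvalues(c(0.5, 0)), NULL)
})
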