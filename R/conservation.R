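#' Mean conservation over intervals
#'
#' Averages per-base track scores over each interval. Uncovered bases
#' contribute 0 to the mean (the "mean0" convention of
#' bigWigAverageOverBed), because unalignable bases left uncovered by a
#' phastCons track carry no evidence of conservation; `covered_only = TRUE`
#' switches to averaging over covered bases alone.
#'
#' @param intervals data.frame with `chrom`, `start`, `end`.
#' @param track `cons_track` from [read_track()].
#' @param covered_only average over covered bases instead of all bases.
#' @return data.frame: the intervals plus `mean_score` and
#'   `covered_fraction`.
#' @export
mean_conservation <- function(intervals, track, covered_only = FALSE) {
  n <- nrow(intervals)
  mean_score <- numeric(n)
  covered_fraction <- numeric(n)
  if (n > 0 && any(!intervals$chrom %in% names(track))) {
    warning("interval(s) on chromosome(s) absent from the track: mean 0, coverage 0",
            call. = FALSE)
  }
  for (chrom in unique(intervals$chrom)) {
    rows <- which(intervals$chrom == chrom)
    width <- intervals$end[rows] - intervals$start[rows]
    pos <- unlist(lapply(rows, function(i) intervals$start[i]:(intervals$end[i] - 1)),
                  use.names = FALSE)
    sc <- track_scores(track, chrom, pos)
    idx <- rep(seq_along(rows), width)
    covered <- !is.na(sc)
    sc[!covered] <- 0
    sums <- tapply(sc, idx, sum)
    ncov <- tapply(covered, idx, sum)
    denom <- if (covered_only) pmax(1, as.numeric(ncov)) else width
    mean_score[rows] <- as.numeric(sums) / denom
    covered_fraction[rows] <- as.numeric(ncov) / width
  }
  intervals$mean_score <- mean_score
  intervals$covered_fraction <- covered_fraction
  intervals
}

#' Sample random noncoding background intervals
#'
#' Draws fixed-length intervals uniformly over the genome by rejection
#' sampling against an exclusion set (coding exons and assembly gaps), the
#' procedure behind the 10,000 x 150 bp random noncoding background used
#' for the enhancer conservation contrast. Sampled intervals may overlap
#' one another.
#'
#' @param genome_sizes named numeric vector of chromosome lengths.
#' @param exclusion data.frame of intervals to avoid (>= 1 bp overlap
#'   rejected); `NULL` for none.
#' @param n number of intervals (default 10000).
#' @param length interval length in bp (default 150).
#' @param seed integer seed; the draw is reproducible.
#' @param max_tries rejection-sampling cap, in multiples of `n`.
#' @return data.frame of `n` intervals with `chrom`, `start`, `end`, `name`.
#' @export
sample_background <- function(genome_sizes, exclusion = NULL, n = 10000L,
                              length = 150L, seed = 1L, max_tries = 1000L) {
  stopifnot(all(genome_sizes > 0), n > 0, length > 0)
  eligible <- genome_sizes[genome_sizes >= length]
  if (!length(eligible)) stop("no chromosome can hold an interval of length ", length,
                              call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  got <- list(); n_got <- 0L; tries <- 0L
  starts_possible <- eligible - length + 1
  repeat {
    batch <- max(n - n_got, 1000L)
    chrom <- sample(names(eligible), batch, replace = TRUE,
                    prob = starts_possible / sum(starts_possible))
    start <- floor(stats::runif(batch) * starts_possible[chrom])
    cand <- data.frame(chrom = chrom, start = start, end = start + length,
                       stringsAsFactors = FALSE)
    if (!is.null(exclusion) && nrow(exclusion)) {
      hit <- unique(interval_overlaps(cand, exclusion)$a_idx)
      if (length(hit)) cand <- cand[-hit, , drop = FALSE]
    }
    if (nrow(cand)) {
      got[[length(got) + 1L]] <- cand
      n_got <- n_got + nrow(cand)
    }
    tries <- tries + batch
    if (n_got >= n) break
    if (tries > max_tries * n) {
      stop("rejection sampling exhausted after ", tries,
           " draws; the exclusion set may cover the genome", call. = FALSE)
    }
  }
  out <- do.call(rbind, got)[seq_len(n), , drop = FALSE]
  out$name <- sprintf("bg%05d", seq_len(n))
  rownames(out) <- NULL
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration (no ties, min(n, m) <= 8) or the normal approximation
#' with tie and continuity corrections otherwise; the reporting convention
#' matches the Mann-Whitney statistic for the first sample.
#'
#' @param scores_a,scores_b numeric samples (nonempty).
#' @return list with `statistic` (W) and `p_value` (two-sided).
#' @export
rank_sum_test <- function(scores_a, scores_b) {
  stopifnot(length(scores_a) > 0, length(scores_b) > 0)
  if (length(unique(c(scores_a, scores_b))) == 1L) {
    return(list(statistic = length(scores_a) * length(scores_b) / 2, p_value = 1))
  }
  ties <- anyDuplicated(c(scores_a, scores_b)) > 0L
  exact <- !ties && min(length(scores_a), length(scores_b)) <= 8L
  ht <- suppressWarnings(
    stats::wilcox.test(scores_a, scores_b, alternative = "two.sided",
                       exact = exact, correct = TRUE)
  )
  list(statistic = unname(ht$statistic), p_value = min(1, ht$p.value))
}

#' Classify element-level conservation
#'
#' @param mean_score numeric phastCons means in `[0, 1]`.
#' @return character: `"ultra"` (>= 0.8), `"conserved"` (>= 0.6), else
#'   `"none"`; boundaries inclusive.
#' @export
classify_conservation <- function(mean_score) {
  stopifnot(all(is.finite(mean_score)))
  ifelse(mean_score >= 0.8, "ultra",
         ifelse(mean_score >= 0.6, "conserved", "none"))
}

#' Filter single-base variants by per-base phyloP score
#'
#' @param variants data.frame of single-base variants (`chrom`, `start`).
#' @param phylop_track `cons_track` of per-base phyloP scores.
#' @param min_score retention threshold, inclusive (default 6.0).
#' @return variants whose base scores >= `min_score`; uncovered bases are
#'   dropped with a warning.
#' @export
filter_conserved_snps <- function(variants, phylop_track, min_score = 6.0) {
  if (nrow(variants) == 0L) return(variants)
  score <- rep(NA_real_, nrow(variants))
  for (chrom in unique(variants$chrom)) {
    rows <- which(variants$chrom == chrom)
    score[rows] <- track_scores(phylop_track, chrom, variants$start[rows])
  }
  if (anyNA(score)) {
    warning(sum(is.na(score)), " variant(s) at uncovered bases dropped", call. = FALSE)
  }
  out <- variants[!is.na(score) & score >= min_score, , drop = FALSE]
  rownames(out) <- NULL
  out
}
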