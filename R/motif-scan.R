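#' Build a position weight matrix with an exact score distribution
#'
#' Converts a 4 x L count matrix to log2-odds with pseudocounts,
#' `log2((counts + pc * bg) / (total + pc) / bg)`, then discretises the
#' scores on an integer grid (default 1/1000 bits) and convolves the
#' per-position score distributions under the background model by dynamic
#' programming. The resulting null distribution makes per-hit p-values
#' exact at grid resolution, the same device FIMO uses.
#'
#' @param counts 4 x L nonnegative matrix, rows A,C,G,T.
#' @param background base frequencies (A,C,G,T), summing to 1.
#' @param pseudocount total pseudocount mass per column (default 0.1).
#' @param grid score grid step in bits (default 0.001).
#' @param motif_id,name identifiers carried through to hits.
#' @return object of class `pwm`.
#' @export
build_pwm <- function(counts, background = rep(0.25, 4), pseudocount = 0.1,
                      grid = 0.001, motif_id = "motif", name = motif_id) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("counts must have 4 rows (A,C,G,T)", call. = FALSE)
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  if (any(colSums(counts) == 0)) stop("all-zero count column", call. = FALSE)
  if (any(background <= 0)) stop("background frequencies must be positive", call. = FALSE)
  background <- background / sum(background)
  totals <- colSums(counts)
  prob <- sweep(counts + pseudocount * background, 2, totals + pseudocount, "/")
  log_odds <- log2(prob / background)
  int_scores <- round(log_odds / grid)
  # DP convolution of per-column integer score distributions under background
  cur <- 1; cur_min <- 0L
  for (i in seq_len(ncol(int_scores))) {
    col <- int_scores[, i]
    new_min <- cur_min + min(col)
    new_len <- (cur_min + max(col)) - new_min + length(cur)
    nxt <- numeric(new_len)
    for (b in 1:4) {
      sh <- cur_min + col[b] - new_min
      idx <- seq_along(cur) + sh
      nxt[idx] <- nxt[idx] + background[b] * cur
    }
    cur <- nxt; cur_min <- new_min
  }
  structure(list(motif_id = motif_id, name = name, log_odds = log_odds,
                 int_scores = int_scores, grid = grid, background = background,
                 pseudocount = pseudocount, dist = cur, dist_min = cur_min),
            class = "pwm")
}

#' Exact p-value of a PWM score
#'
#' `P(null score >= observed)` under the PWM's discretised background score
#' distribution. Scores are in bits; the observed score is snapped to the
#' PWM's grid.
#'
#' @param pwm a [build_pwm()] object.
#' @param score observed score in bits (may be vectorised).
#' @return p-values in `(0, 1]`.
#' @export
score_pvalue <- function(pwm, score) {
  surv <- rev(cumsum(rev(pwm$dist)))   # surv[k] = P(S_int >= dist_min + k - 1)
  smallest_pos <- surv[max(which(surv > 0))]
  s_int <- as.integer(round(score / pwm$grid))
  k <- s_int - pwm$dist_min + 1L
  p <- numeric(length(k))
  below <- k < 1L
  above <- k > length(surv)
  p[below] <- 1
  if (any(above)) {
    warning("score above the maximum achievable; returning smallest positive mass",
            call. = FALSE)
    p[above] <- smallest_pos
  }
  mid <- !below & !above
  p[mid] <- surv[k[mid]]
  p[p <= 0] <- smallest_pos
  p
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment, `q_(i) = min_{j >= i} p_(j) * m / j`, returned in
#' the input order.
#'
#' @param p_values numeric vector in `(0, 1]`.
#' @return q-values in `(0, 1]`.
#' @export
bh_qvalues <- function(p_values) {
  stopifnot(all(p_values > 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "BH")
}

DNA_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L)

revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

# Integer scores of every motif placement on one encoded sequence;
# N positions contribute the background-expected column score.
score_positions <- function(codes, int_scores, expected_int) {
  L <- ncol(int_scores)
  npos <- length(codes) - L + 1L
  if (npos < 1L) return(numeric(0))
  sc <- numeric(npos)
  for (i in seq_len(L)) {
    v <- int_scores[codes[seq_len(npos) + i - 1L], i]
    v[is.na(v)] <- expected_int[i]
    sc <- sc + v
  }
  sc
}

#' Scan sequences with PWMs
#'
#' Scores every placement of every motif on both strands, converts scores to
#' exact p-values via each PWM's null distribution, and computes BH q-values
#' across ALL scanned (motif, position, strand) tests — the multiple-testing
#' universe FIMO adjusts over — before filtering to `p <= p_threshold`.
#'
#' @param sequences named character vector over A,C,G,T,N (e.g.
#'   [read_fasta()] output).
#' @param pwms list of [build_pwm()] objects.
#' @param p_threshold per-hit p-value cutoff (default 1e-4).
#' @return data.frame of hits: `motif_id`, `seq_name`, `offset` (0-based,
#'   forward-strand coordinates of the match start), `strand`, `score`
#'   (bits), `p_value`, `q_value`, `best` (best hit per motif x sequence);
#'   attribute `n_tests` records the adjustment universe size.
#' @export
scan_motifs <- function(sequences, pwms, p_threshold = 1e-4) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    names(sequences) <- paste0("seq", seq_along(sequences))
  }
  rows <- list()
  for (pwm in pwms) {
    L <- ncol(pwm$int_scores)
    expected_int <- colSums(pwm$int_scores * pwm$background)
    for (sn in names(sequences)) {
      fwd <- toupper(sequences[[sn]])
      slen <- nchar(fwd)
      if (slen < L) next
      for (strand in c("+", "-")) {
        s <- if (strand == "+") fwd else revcomp(fwd)
        codes <- unname(DNA_CODE[strsplit(s, "")[[1]]])
        sc <- score_positions(codes, pwm$int_scores, expected_int)
        if (!length(sc)) next
        offset <- if (strand == "+") seq_along(sc) - 1L else slen - (seq_along(sc) - 1L) - L
        rows[[length(rows) + 1L]] <- data.frame(
          motif_id = pwm$motif_id, seq_name = sn, offset = offset,
          strand = strand, score = sc * pwm$grid,
          p_value = score_pvalue(pwm, sc * pwm$grid),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    out <- data.frame(motif_id = character(0), seq_name = character(0),
                      offset = integer(0), strand = character(0),
                      score = numeric(0), p_value = numeric(0),
                      q_value = numeric(0), best = logical(0))
    attr(out, "n_tests") <- 0L
    return(out)
  }
  all_hits <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  n_tests <- nrow(all_hits)
  all_hits$q_value <- bh_qvalues(all_hits$p_value)
  hits <- all_hits[all_hits$p_value <= p_threshold, , drop = FALSE]
  if (nrow(hits)) {
    hits <- hits[order(hits$motif_id, hits$seq_name, hits$p_value,
                       hits$offset, hits$strand), , drop = FALSE]
    hits$best <- !duplicated(paste(hits$motif_id, hits$seq_name))
  } else {
    hits$best <- logical(0)
  }
  rownames(hits) <- NULL
  attr(hits, "n_tests") <- n_tests
  hits
}

#' Motif-level significance summary
#'
#' One row per (motif, sequence) pair: the pair's best hit and its q-value
#' (BH-adjusted over the full scan universe), the reporting unit used to
#' count significantly enriched transcription-factor binding sites.
#'
#' @param hits output of [scan_motifs()].
#' @param q_threshold motif retention threshold (default 0.05, inclusive).
#' @return data.frame of best hits with `significant` flag, ordered by
#'   q-value.
#' @export
motif_significance <- function(hits, q_threshold = 0.05) {
  best <- hits[hits$best, , drop = FALSE]
  best$significant <- best$q_value <= q_threshold
  best <- best[order(best$q_value, best$p_value, best$motif_id), , drop = FALSE]
  rownames(best) <- NULL
  best
}
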