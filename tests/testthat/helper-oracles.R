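# Independent brute-force oracles used to pin the fast implementations.

# All-pairs interval overlap scan, O(n * m).
oracle_overlaps <- function(a, b, min_overlap = 1L) {
  out <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j]) {
        ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
        if (ov >= min_overlap) out[[length(out) + 1L]] <- c(i, j)
      }
    }
  }
  if (!length(out)) return(data.frame(a_idx = integer(0), b_idx = integer(0)))
  m <- do.call(rbind, out)
  data.frame(a_idx = m[, 1], b_idx = m[, 2])
}

# Exact two-sided Wilcoxon rank-sum p-value by full enumeration of all
# choose(n + m, n) rank assignments (no ties assumed).
oracle_rank_sum_p <- function(a, b) {
  n <- length(a); m <- length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2   # Mann-Whitney U for sample a
  combos <- utils::combn(n + m, n)
  u_all <- apply(combos, 2, function(idx) sum(rank(seq_len(n + m))[idx]) - n * (n + 1) / 2)
  lower <- mean(u_all <= w_obs)
  upper <- mean(u_all >= w_obs)
  min(1, 2 * min(lower, upper))
}

# Exact PWM hit p-value by enumerating all 4^L sequences under the
# background model, scored on the PWM's discretised integer grid.
oracle_pwm_pvalue <- function(pwm, score) {
  L <- ncol(pwm$int_scores)
  grid_codes <- as.matrix(expand.grid(rep(list(1:4), L)))
  probs <- apply(grid_codes, 1, function(codes) prod(pwm$background[codes]))
  scores <- apply(grid_codes, 1, function(codes) {
    sum(pwm$int_scores[cbind(codes, seq_len(L))])
  })
  s_int <- round(score / pwm$grid)
  sum(probs[scores >= s_int])
}

rdirichlet1 <- function(alpha) {
  x <- rgamma(length(alpha), alpha)
  x / sum(x)
}

# Random two-chain toy structure for distance-rule oracles.
random_toy_atoms <- function(seed, n_a = 15L, n_b = 15L) {
  set.seed(seed)
  data.frame(
    chain = rep(c("A", "B"), c(n_a, n_b)),
    resno = c(sample(1:5, n_a, replace = TRUE), sample(1:5, n_b, replace = TRUE)),
    resid = "ALA", elety = "CA",
    x = runif(n_a + n_b, 0, 12), y = runif(n_a + n_b, 0, 12),
    z = runif(n_a + n_b, 0, 12), stringsAsFactors = FALSE)
}

atom_dist <- function(atoms, i, j) {
  sqrt(sum((unlist(atoms[i, c("x", "y", "z")]) -
              unlist(atoms[j, c("x", "y", "z")]))^2))
}

# Brute-force interface flags per (chain, resno).
oracle_interface <- function(atoms, chain_a, chain_b, cutoff = 5.0) {
  res <- unique(atoms[atoms$chain %in% c(chain_a, chain_b), c("chain", "resno")])
  res$interface <- FALSE
  for (k in seq_len(nrow(res))) {
    other_chain <- if (res$chain[k] == chain_a) chain_b else chain_a
    own <- which(atoms$chain == res$chain[k] & atoms$resno == res$resno[k])
    oth <- which(atoms$chain == other_chain)
    for (i in own) for (j in oth) {
      if (atom_dist(atoms, i, j) <= cutoff) res$interface[k] <- TRUE
    }
  }
  res[order(res$chain, res$resno), , drop = FALSE]
}

oracle_contacts <- function(atoms, chain, resno, cutoff = 4.0) {
  own <- which(atoms$chain == chain & atoms$resno == resno)
  oth <- setdiff(seq_len(nrow(atoms)), own)
  n <- 0L
  for (j in oth) {
    if (any(vapply(own, function(i) atom_dist(atoms, i, j) <= cutoff, logical(1)))) {
      n <- n + 1L
    }
  }
  n
}
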