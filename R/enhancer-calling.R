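#' Expand SNPs into fixed-width candidate enhancer windows
#'
#' Each single-base SNP is expanded by `flank` bp on both sides, giving the
#' half-open window `[snp_start - flank, snp_start + flank)` of length
#' `2 * flank` (150 bp at the default flank of 75). Windows are clipped at
#' position 0 and, when `chrom_sizes` is supplied, at the chromosome end;
#' clipped windows carry a `truncated` flag. A zero flank degenerates to the
#' SNP base itself and is flagged.
#'
#' @param variants variant data.frame of single-base SNPs (`chrom`, `start`,
#'   `end`, `rsid`, `source`; `end - start` must be 1).
#' @param flank bp added on each side (default 75).
#' @param chrom_sizes optional named vector of chromosome lengths for
#'   right-clipping.
#' @return window data.frame: `chrom`, `start`, `end`, `rsid`, `source`,
#'   `snp_start`, `truncated`, `degenerate`.
#' @export
expand_windows <- function(variants, flank = 75L, chrom_sizes = NULL) {
  if (flank < 0) stop("flank must be >= 0", call. = FALSE)
  if (nrow(variants) == 0L) {
    return(data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                      rsid = character(0), source = character(0),
                      snp_start = numeric(0), truncated = logical(0),
                      degenerate = logical(0), stringsAsFactors = FALSE))
  }
  len <- variants$end - variants$start
  if (any(len != 1) ||
      ("variant_type" %in% names(variants) && any(variants$variant_type != "snp"))) {
    stop("windows are defined for single-base SNPs only", call. = FALSE)
  }
  degenerate <- flank == 0
  start <- if (degenerate) variants$start else variants$start - flank
  end <- if (degenerate) variants$end else variants$start + flank
  truncated <- start < 0
  start <- pmax(0, start)
  if (!is.null(chrom_sizes)) {
    size <- chrom_sizes[variants$chrom]
    over <- !is.na(size) & end > size
    truncated <- truncated | over
    end <- ifelse(over, size, end)
  }
  data.frame(chrom = variants$chrom, start = start, end = end,
             rsid = variants$rsid, source = variants$source,
             snp_start = variants$start, truncated = truncated,
             degenerate = degenerate, stringsAsFactors = FALSE)
}

#' Stage-by-mark activity of candidate windows
#'
#' A (stage, mark) cell is active for a window iff some peak of that stage
#' and mark overlaps the window by at least 1 bp AND has
#' `pval_signal >= threshold` (inclusive). The best overlapping signal per
#' cell is recorded regardless of the threshold.
#'
#' @param windows window data.frame from [expand_windows()].
#' @param peaks peak data.frame from [read_peak_dir()]/[read_narrowpeak()].
#' @param threshold -log10 p-value signal cutoff (default 9.0).
#' @return long data.frame: `window_idx`, `stage`, `mark`, `best_signal`
#'   (`NA` when no peak overlaps), `active`.
#' @export
stage_activity <- function(windows, peaks, threshold = 9.0) {
  stopifnot(threshold > 0)
  if (!all(peaks$stage %in% CARNEGIE_STAGES) || !all(peaks$mark %in% HISTONE_MARKS)) {
    stop("peaks carry stage/mark outside the fixed vocabularies", call. = FALSE)
  }
  grid <- expand.grid(window_idx = seq_len(nrow(windows)),
                      stage = CARNEGIE_STAGES, mark = HISTONE_MARKS,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$best_signal <- NA_real_
  if (nrow(windows) > 0L && nrow(peaks) > 0L) {
    ov <- interval_overlaps(windows, peaks)
    if (nrow(ov)) {
      key <- paste(ov$a_idx, peaks$stage[ov$b_idx], peaks$mark[ov$b_idx])
      best <- tapply(peaks$pval_signal[ov$b_idx], key, max)
      gkey <- paste(grid$window_idx, grid$stage, grid$mark)
      hit <- match(gkey, names(best))
      grid$best_signal <- as.numeric(best[hit])
    }
  }
  grid$active <- !is.na(grid$best_signal) & grid$best_signal >= threshold
  grid[order(grid$window_idx, grid$stage, grid$mark), , drop = FALSE]
}

# Stage-level activity under the mark rule: "any" mark, "all" marks, or a
# single named mark.
stage_active_table <- function(activity, mark_rule = "any") {
  agg_fun <- if (identical(mark_rule, "any")) {
    any
  } else if (identical(mark_rule, "all")) {
    all
  } else if (mark_rule %in% HISTONE_MARKS) {
    identity
  } else {
    stop("mark_rule must be 'any', 'all', or one of ", paste(HISTONE_MARKS, collapse = ", "),
         call. = FALSE)
  }
  sub <- if (mark_rule %in% HISTONE_MARKS) {
    activity[activity$mark == mark_rule, , drop = FALSE]
  } else activity
  stats::aggregate(active ~ window_idx + stage, data = sub,
                   FUN = function(v) agg_fun(v))
}

#' Call putative enhancers from window activity
#'
#' A window is called an enhancer iff it is stage-active in at least one
#' Carnegie stage under `mark_rule`. Calls with byte-identical intervals
#' from different source catalogues are merged into one call with combined
#' provenance.
#'
#' @param windows window data.frame from [expand_windows()].
#' @param activity output of [stage_activity()] for the same windows.
#' @param mark_rule "any" (default: any of the three marks passes), "all",
#'   or one mark name.
#' @return enhancer call data.frame: `chrom`, `start`, `end`, `rsid`,
#'   `snp_start`, `provenance` (comma-joined sources), `active_stages`
#'   (comma-joined), `n_active_stages`, `max_signal`.
#' @export
call_enhancers <- function(windows, activity, mark_rule = "any") {
  empty <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                      rsid = character(0), snp_start = numeric(0),
                      provenance = character(0), active_stages = character(0),
                      n_active_stages = integer(0), max_signal = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(windows) == 0L) return(empty)
  st <- stage_active_table(activity, mark_rule)
  st <- st[st$active, , drop = FALSE]
  if (nrow(st) == 0L) return(empty)
  stages_by_win <- tapply(st$stage, st$window_idx, function(s) {
    paste(CARNEGIE_STAGES[CARNEGIE_STAGES %in% s], collapse = ",")
  })
  idx <- as.integer(names(stages_by_win))
  max_sig <- tapply(activity$best_signal, activity$window_idx,
                    function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  calls <- data.frame(
    chrom = windows$chrom[idx], start = windows$start[idx], end = windows$end[idx],
    rsid = windows$rsid[idx], snp_start = windows$snp_start[idx],
    provenance = windows$source[idx],
    active_stages = as.character(stages_by_win),
    stringsAsFactors = FALSE
  )
  calls$max_signal <- as.numeric(max_sig[as.character(idx)])
  # merge byte-identical intervals across sources
  key <- paste(calls$chrom, calls$start, calls$end)
  merged <- lapply(split(seq_len(nrow(calls)), key), function(i) {
    one <- calls[i[1], , drop = FALSE]
    one$provenance <- paste(sort(unique(calls$provenance[i])), collapse = ",")
    one$rsid <- paste(sort(unique(calls$rsid[i])), collapse = ",")
    stages <- unique(unlist(strsplit(calls$active_stages[i], ",")))
    one$active_stages <- paste(CARNEGIE_STAGES[CARNEGIE_STAGES %in% stages],
                               collapse = ",")
    one$max_signal <- max(calls$max_signal[i])
    one
  })
  out <- do.call(rbind, c(merged, list(make.row.names = FALSE)))
  out$n_active_stages <- lengths(strsplit(out$active_stages, ","))
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify developmental stage categories
#'
#' With the stage groups early = CS13,CS14,CS16; intermediate =
#' CS17,CS18,CS19; late = CS20,CS21,CS23, the category of a call is
#' determined by which groups are FULLY contained in its active stage set:
#' one group gives `early`/`intermediate`/`late`, two give the pairwise
#' categories, all three give `always_active` (constitutive activity), and
#' no fully contained group gives `unclassified`.
#'
#' @param calls enhancer call data.frame with `active_stages`.
#' @param min_stages optional minimum number of active stages a call must
#'   show before classification (calls below it are dropped); `NULL`
#'   (default) disables this pre-filter.
#' @return `calls` with a `stage_category` column (pre-filter applied).
#' @export
classify_stage_category <- function(calls, min_stages = NULL) {
  if (!is.null(min_stages)) {
    calls <- calls[lengths(strsplit(calls$active_stages, ",")) >= min_stages, ,
                   drop = FALSE]
  }
  label_for <- c("100" = "early", "010" = "intermediate", "001" = "late",
                 "110" = "early_intermediate", "101" = "early_late",
                 "011" = "intermediate_late", "111" = "always_active",
                 "000" = "unclassified")
  calls$stage_category <- vapply(strsplit(calls$active_stages, ","), function(s) {
    if (length(s) == 0L || !nzchar(s[1])) stop("empty active stage set", call. = FALSE)
    contained <- vapply(STAGE_GROUPS, function(g) all(g %in% s), logical(1))
    label_for[paste(as.integer(contained), collapse = "")]
  }, character(1), USE.NAMES = FALSE)
  rownames(calls) <- NULL
  calls
}

#' Drop enhancers containing well-reviewed benign variants
#'
#' A call is removed iff a benign-classified ClinVar variant with a review
#' status of `min_excluded_stars` or more stars (default 2, i.e. "above
#' star 1") falls inside its interval.
#'
#' @param calls enhancer call data.frame.
#' @param clinvar_records variant data.frame with `clinical_significance`
#'   and `review_stars`.
#' @param min_excluded_stars minimum star rating that triggers exclusion.
#' @return filtered calls.
#' @export
exclude_benign <- function(calls, clinvar_records, min_excluded_stars = 2L) {
  if (nrow(calls) == 0L || nrow(clinvar_records) == 0L) return(calls)
  sig <- normalize_trait(clinvar_records$clinical_significance)
  benign <- clinvar_records[
    sig %in% c("benign", "likely benign", "benign/likely benign") &
      !is.na(clinvar_records$review_stars) &
      clinvar_records$review_stars >= min_excluded_stars, , drop = FALSE]
  if (nrow(benign) == 0L) return(calls)
  drop <- unique(interval_overlaps(calls, benign)$a_idx)
  out <- calls[setdiff(seq_len(nrow(calls)), drop), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-reference calls against a known enhancer set
#'
#' @param calls enhancer call data.frame.
#' @param known data.frame of known enhancer intervals (e.g. [read_bed()]).
#' @return list: `pairs` (call_idx, known_idx for every >= 1 bp overlap) and
#'   `n_calls_overlapping` (each call counted once).
#' @export
cross_reference <- function(calls, known) {
  ov <- interval_overlaps(calls, known)
  list(pairs = data.frame(call_idx = ov$a_idx, known_idx = ov$b_idx),
       n_calls_overlapping = length(unique(ov$a_idx)))
}
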