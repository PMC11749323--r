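#' Genomic intervals (0-based, half-open)
#'
#' All coordinates inside the package follow the BED convention: 0-based
#' starts, exclusive ends. One-based inputs (catalogue positions, fixedStep
#' wiggle headers) are converted at parse time. These helpers construct and
#' validate plain data frames with columns `chrom`, `start`, `end`, `name`;
#' overlap queries are delegated to [GenomicRanges::findOverlaps()] after an
#' internal shift to 1-based closed coordinates.
#'
#' @param chrom character chromosome names ("chr" prefix enforced).
#' @param start,end integer-valued 0-based half-open bounds; `end > start`.
#' @param name optional labels (recycled).
#' @return data.frame with class `c("gintervals", "data.frame")`.
#' @export
gintervals <- function(chrom, start, end, name = NA_character_) {
  chrom <- normalize_chrom(as.character(chrom))
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- max(length(chrom), length(start), length(end))
  if (n > 0) {
    chrom <- rep_len(chrom, n); start <- rep_len(start, n)
    end <- rep_len(end, n); name <- rep_len(as.character(name), n)
  } else {
    name <- character(0)
  }
  bad <- which(!is.finite(start) | !is.finite(end) | start < 0 | end <= start)
  if (length(bad)) {
    stop("invalid interval(s) at row(s) ", paste(utils::head(bad, 5), collapse = ", "),
         ": require 0 <= start < end", call. = FALSE)
  }
  out <- data.frame(chrom = chrom, start = start, end = end, name = name,
                    stringsAsFactors = FALSE)
  class(out) <- c("gintervals", "data.frame")
  out
}

#' @rdname gintervals
#' @param x object with `chrom`, `start`, `end` columns.
#' @export
as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

# Enforce the "chr" prefix on ingest.
normalize_chrom <- function(chrom) {
  ifelse(grepl("^chr", chrom) | is.na(chrom), chrom, paste0("chr", chrom))
}

#' Overlap pairs between two interval sets
#'
#' Returns every pair overlapping by at least `min_overlap` bp, as row
#' indices into `a` and `b`.
#'
#' @param a,b data frames with `chrom`, `start`, `end` (0-based half-open).
#' @param min_overlap minimum overlap in bp (default 1).
#' @return data.frame with columns `a_idx`, `b_idx`.
#' @export
interval_overlaps <- function(a, b, min_overlap = 1L) {
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(data.frame(a_idx = integer(0), b_idx = integer(0)))
  }
  hits <- GenomicRanges::findOverlaps(as_granges(a), as_granges(b),
                                      minoverlap = min_overlap)
  data.frame(a_idx = S4Vectors::queryHits(hits),
             b_idx = S4Vectors::subjectHits(hits))
}

#' Write intervals as BED
#'
#' BED3 when no names/scores are available, BED6 otherwise. Plain-text,
#' tab-separated, no header.
#'
#' @param x intervals data frame; optional `name`, `score`, `strand` columns.
#' @param path output file.
#' @export
write_bed <- function(x, path) {
  name <- if ("name" %in% names(x)) ifelse(is.na(x$name), ".", x$name) else NULL
  if (is.null(name)) {
    df <- data.frame(x$chrom, format_coord(x$start), format_coord(x$end))
  } else {
    score <- if ("score" %in% names(x)) x$score else 0
    strand <- if ("strand" %in% names(x)) x$strand else "."
    df <- data.frame(x$chrom, format_coord(x$start), format_coord(x$end),
                     name, score, strand)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED3/BED6 file
#'
#' @param path BED file (no header).
#' @return `gintervals` data frame; BED6 inputs keep `score` and `strand`.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 3L) stop("BED file needs at least 3 columns: ", path, call. = FALSE)
  out <- gintervals(df[[1]], df[[2]], df[[3]],
                    name = if (ncol(df) >= 4L) df[[4]] else NA_character_)
  if (ncol(df) >= 6L) {
    out$score <- df[[5]]
    out$strand <- df[[6]]
  }
  out
}

# Integers printed without scientific notation.
format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)
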