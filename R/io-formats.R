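#' Read an ENCODE narrowPeak file
#'
#' narrowPeak is BED6+4; the peak-confidence score used throughout the
#' pipeline ("pvalSignal", a -log10 p-value) is taken from column 8 by
#' default. The column index is configurable because track hubs differ in
#' whether signalValue (column 7) or pValue (column 8) carries the score.
#'
#' @param path narrowPeak file.
#' @param mark histone mark, one of [HISTONE_MARKS].
#' @param stage Carnegie stage, one of [CARNEGIE_STAGES].
#' @param pval_col 1-based column holding the -log10 p-value signal.
#' @return data.frame: `chrom`, `start`, `end`, `name`, `mark`, `stage`,
#'   `pval_signal`; one row per peak.
#' @export
read_narrowpeak <- function(path, mark, stage, pval_col = 8L) {
  mark <- match.arg(mark, HISTONE_MARKS)
  stage <- match.arg(stage, CARNEGIE_STAGES)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                      name = character(0), mark = character(0), stage = character(0),
                      pval_signal = numeric(0), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 10L)) {
    stop("narrowPeak parse error in ", path, ": line(s) ",
         paste(utils::head(which(nf < 10L), 5), collapse = ", "),
         " have fewer than 10 columns", call. = FALSE)
  }
  mat <- do.call(rbind, fields)
  pval <- suppressWarnings(as.numeric(mat[, pval_col]))
  if (anyNA(pval)) {
    stop("narrowPeak parse error in ", path, ": non-numeric pval signal at line(s) ",
         paste(utils::head(which(is.na(pval)), 5), collapse = ", "), call. = FALSE)
  }
  start <- suppressWarnings(as.numeric(mat[, 2]))
  end <- suppressWarnings(as.numeric(mat[, 3]))
  bad <- which(is.na(start) | is.na(end) | end <= start | start < 0)
  if (length(bad)) {
    stop("narrowPeak parse error in ", path, ": invalid interval at line(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (any(pval < 0)) {
    stop("narrowPeak parse error in ", path, ": negative pval signal", call. = FALSE)
  }
  data.frame(chrom = normalize_chrom(mat[, 1]), start = start, end = end,
             name = mat[, 4], mark = mark, stage = stage, pval_signal = pval,
             stringsAsFactors = FALSE)
}

#' Read all stage/mark narrowPeak tracks from a directory
#'
#' Expects files named `<stage>_<mark>.narrowPeak`; absent files are treated
#' as empty tracks.
#'
#' @param dir directory of narrowPeak files.
#' @inheritParams read_narrowpeak
#' @return one data.frame of peaks (rbind of [read_narrowpeak()] outputs).
#' @export
read_peak_dir <- function(dir, pval_col = 8L) {
  out <- list()
  for (stage in CARNEGIE_STAGES) {
    for (mark in HISTONE_MARKS) {
      f <- file.path(dir, paste0(stage, "_", mark, ".narrowPeak"))
      if (file.exists(f)) {
        out[[paste(stage, mark, sep = "_")]] <-
          read_narrowpeak(f, mark = mark, stage = stage, pval_col = pval_col)
      }
    }
  }
  if (length(out) == 0L) stop("no narrowPeak files found under ", dir, call. = FALSE)
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Read JASPAR 2022 position frequency matrices
#'
#' Parses the plain-text JASPAR format: a `>ID NAME` header followed by four
#' rows `A [ 1 2 3 ]` ... in A, C, G, T order.
#'
#' @param path JASPAR PFM text file (one or more motifs).
#' @return named list (by motif ID) of 4 x L count matrices with rownames
#'   A,C,G,T and a `name` attribute.
#' @export
read_jaspar_pfm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("no JASPAR motif headers in ", path, call. = FALSE)
  out <- list()
  bounds <- c(hdr, length(lines) + 1L)
  for (k in seq_along(hdr)) {
    block <- lines[(bounds[k] + 1L):(bounds[k + 1L] - 1L)]
    header <- sub("^>\\s*", "", lines[hdr[k]])
    parts <- strsplit(trimws(header), "\\s+")[[1]]
    id <- parts[1]
    name <- if (length(parts) > 1L) paste(parts[-1], collapse = " ") else id
    if (length(block) != 4L) {
      stop("motif ", id, ": expected 4 base rows, got ", length(block), call. = FALSE)
    }
    rows <- lapply(block, function(l) {
      body <- sub("^\\s*[ACGTacgt]", "", l)
      as.numeric(regmatches(body, gregexpr("-?[0-9.]+", body))[[1]])
    })
    lens <- lengths(rows)
    if (length(unique(lens)) != 1L) {
      stop("motif ", id, ": base rows have unequal lengths (",
           paste(lens, collapse = ","), ")", call. = FALSE)
    }
    m <- do.call(rbind, rows)
    rownames(m) <- c("A", "C", "G", "T")
    if (any(m < 0)) stop("motif ", id, ": negative counts", call. = FALSE)
    attr(m, "name") <- name
    out[[id]] <- m
  }
  out
}

#' Write motifs in JASPAR PFM text format
#'
#' @param pfms named list of 4 x L count matrices (as from [read_jaspar_pfm()]).
#' @param path output file.
#' @export
write_jaspar_pfm <- function(pfms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(pfms)) {
    m <- pfms[[id]]
    name <- attr(m, "name")
    if (is.null(name)) name <- id
    writeLines(paste0(">", id, " ", name), con)
    for (b in c("A", "C", "G", "T")) {
      writeLines(paste0(b, "  [ ", paste(format(m[b, ], trim = TRUE), collapse = " "), " ]"), con)
    }
  }
  invisible(path)
}

#' Read a per-base conservation track
#'
#' Accepts 4-column bedGraph or fixedStep wiggle. Scores are materialised
#' per base (0-based positions); when intervals overlap, the value written
#' last wins and a warning is raised. Uncovered bases are distinct from
#' zero-scored bases: queries on them return `NA`.
#'
#' @param path bedGraph or fixedStep wiggle file.
#' @return object of class `cons_track`: per-chromosome sorted positions and
#'   scores.
#' @export
read_track <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^(track|#)", lines)]
  if (length(lines) == 0L) return(new_cons_track(list()))
  is_wig <- any(grepl("^fixedStep", lines))
  chrom_v <- character(0); pos_v <- integer(0); score_v <- numeric(0)
  if (is_wig) {
    hdrs <- grep("^fixedStep", lines)
    bounds <- c(hdrs, length(lines) + 1L)
    for (k in seq_along(hdrs)) {
      h <- lines[hdrs[k]]
      get_field <- function(key) sub(paste0(".*", key, "=([^ \t]+).*"), "\\1", h)
      chrom <- normalize_chrom(get_field("chrom"))
      start1 <- as.integer(get_field("start"))   # 1-based per wiggle spec
      step <- if (grepl("step=", h)) as.integer(get_field("step")) else 1L
      span <- if (grepl("span=", h)) as.integer(get_field("span")) else 1L
      vals <- as.numeric(lines[(bounds[k] + 1L):(bounds[k + 1L] - 1L)])
      if (anyNA(vals)) stop("non-numeric wiggle value under header: ", h, call. = FALSE)
      starts0 <- start1 - 1L + step * (seq_along(vals) - 1L)
      pos <- rep(starts0, each = span) + rep.int(seq_len(span) - 1L, length(vals))
      chrom_v <- c(chrom_v, rep(chrom, length(pos)))
      pos_v <- c(pos_v, pos)
      score_v <- c(score_v, rep(vals, each = span))
    }
  } else {
    fields <- strsplit(lines, "[ \t]+")
    if (any(lengths(fields) < 4L)) {
      stop("unknown track format (need bedGraph 4 columns or fixedStep wiggle): ",
           path, call. = FALSE)
    }
    mat <- do.call(rbind, fields)
    start <- as.integer(mat[, 2]); end <- as.integer(mat[, 3])
    val <- as.numeric(mat[, 4])
    if (anyNA(start) || anyNA(end) || anyNA(val)) {
      stop("non-numeric bedGraph fields in ", path, call. = FALSE)
    }
    if (any(end <= start)) stop("bedGraph interval with end <= start in ", path, call. = FALSE)
    w <- end - start
    chrom_v <- rep(normalize_chrom(mat[, 1]), w)
    pos_v <- unlist(lapply(seq_along(start), function(i) start[i]:(end[i] - 1L)),
                    use.names = FALSE)
    score_v <- rep(val, w)
  }
  key <- paste(chrom_v, pos_v)
  dup <- duplicated(key, fromLast = TRUE)
  if (any(dup)) {
    warning("overlapping track intervals in ", path, "; last value wins", call. = FALSE)
    chrom_v <- chrom_v[!dup]; pos_v <- pos_v[!dup]; score_v <- score_v[!dup]
  }
  per_chrom <- split(seq_along(pos_v), chrom_v)
  track <- lapply(per_chrom, function(idx) {
    o <- order(pos_v[idx])
    list(pos = pos_v[idx][o], score = score_v[idx][o])
  })
  new_cons_track(track)
}

new_cons_track <- function(per_chrom) {
  structure(per_chrom, class = "cons_track")
}

#' Query per-base track scores
#'
#' @param track a `cons_track`.
#' @param chrom single chromosome name.
#' @param positions 0-based base positions.
#' @return numeric scores; `NA` for uncovered bases.
#' @export
track_scores <- function(track, chrom, positions) {
  chrom <- normalize_chrom(chrom)
  tr <- track[[chrom]]
  if (is.null(tr)) return(rep(NA_real_, length(positions)))
  tr$score[match(positions, tr$pos)]
}

#' Read a minimal GFF3 gene model
#'
#' Consumes `gene` and `exon` features. Gene biotype is read from the
#' attribute column (`biotype=coding|ncRNA`; defaults to coding). GFF3
#' 1-based closed coordinates are converted to the internal 0-based
#' half-open convention.
#'
#' @param path GFF3 file.
#' @return list with `genes` (name, chrom, start, end, strand, biotype, tss)
#'   and `exons` (gene, chrom, start, end) data frames.
#' @export
read_gene_model <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE, quote = "")
  if (ncol(df) < 9L) stop("GFF3 needs 9 columns: ", path, call. = FALSE)
  names(df) <- c("chrom", "source", "type", "start1", "end1", "score",
                 "strand", "phase", "attr")
  get_attr <- function(attr, key, default = NA_character_) {
    m <- regmatches(attr, regexpr(paste0("(^|;)", key, "=[^;]+"), attr))
    out <- rep(default, length(attr))
    hit <- nchar(m) > 0
    out[hit] <- sub(paste0(".*", key, "="), "", m[hit])
    out
  }
  g <- df[df$type == "gene", ]
  e <- df[df$type == "exon", ]
  biotype <- get_attr(g$attr, "biotype", "coding")
  genes <- data.frame(
    name = get_attr(g$attr, "ID"),
    chrom = normalize_chrom(g$chrom),
    start = g$start1 - 1L, end = g$end1, strand = g$strand,
    biotype = ifelse(biotype %in% c("coding", "ncRNA"), biotype, "coding"),
    stringsAsFactors = FALSE
  )
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  exons <- data.frame(
    gene = get_attr(e$attr, "Parent"),
    chrom = normalize_chrom(e$chrom),
    start = e$start1 - 1L, end = e$end1,
    stringsAsFactors = FALSE
  )
  if (!all(exons$gene %in% genes$name)) {
    stop("exon with unknown Parent gene in ", path, call. = FALSE)
  }
  list(genes = genes, exons = exons)
}

#' Read FASTA sequences
#'
#' @param path FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' Read ATOM records from a PDB file
#'
#' Uses bio3d for parsing; hydrogens are dropped so that downstream distance
#' rules operate on heavy atoms only.
#'
#' @param path PDB file.
#' @return data.frame: `chain`, `resno`, `resid`, `elety`, `x`, `y`, `z`.
#' @export
read_pdb_atoms <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  elem <- trimws(at$elesy)
  no_elem <- is.na(elem) | !nzchar(elem)
  # fall back to the atom-name heuristic when the element column is blank
  elem[no_elem] <- substr(gsub("[0-9]", "", trimws(at$elety[no_elem])), 1, 1)
  at <- at[toupper(elem) != "H", , drop = FALSE]
  data.frame(chain = at$chain, resno = at$resno, resid = at$resid,
             elety = trimws(at$elety), x = at$x, y = at$y, z = at$z,
             stringsAsFactors = FALSE)
}
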