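#' Read a GWAS-catalog-style association table
#'
#' Expects a tab-separated file with header columns `SNPS`, `CHR_ID`,
#' `CHR_POS` (1-based), `DISEASE/TRAIT` and `P-VALUE`. Positions are
#' converted to 0-based half-open single-base intervals.
#'
#' @param path TSV file.
#' @return variant data.frame (see [filter_chd()] for the column contract).
#' @export
read_gwas_catalog <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE,
                          check.names = FALSE)
  need <- c("SNPS", "CHR_ID", "CHR_POS", "DISEASE/TRAIT", "P-VALUE")
  if (!all(need %in% names(df))) {
    stop("GWAS catalogue missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  pos1 <- as.numeric(df$CHR_POS)
  data.frame(
    rsid = df$SNPS,
    chrom = normalize_chrom(as.character(df$CHR_ID)),
    start = pos1 - 1, end = pos1,
    source = "gwas",
    traits = df[["DISEASE/TRAIT"]],
    p_value = suppressWarnings(as.numeric(df[["P-VALUE"]])),
    variant_type = "snp",
    clinical_significance = NA_character_,
    review_stars = NA_integer_,
    stringsAsFactors = FALSE
  )
}

#' Read a ClinVar variant_summary-style table
#'
#' Expects header columns `Name`, `Type`, `ClinicalSignificance`,
#' `ReviewStatus`, `PhenotypeList`, `Chromosome`, `Start`, `Stop`, `RS#`.
#' `Start`/`Stop` are 1-based inclusive and are converted to 0-based
#' half-open. Review-status text is mapped to the 0-4 star scale.
#'
#' @param path TSV file.
#' @return variant data.frame.
#' @export
read_clinvar <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE,
                          check.names = FALSE)
  need <- c("Name", "Type", "ClinicalSignificance", "ReviewStatus",
            "PhenotypeList", "Chromosome", "Start", "Stop", "RS#")
  if (!all(need %in% names(df))) {
    stop("ClinVar table missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  known_types <- c("snp", "single nucleotide variant", "deletion", "duplication",
                   "indel", "insertion", "microsatellite")
  type <- tolower(df$Type)
  unknown <- !(type %in% known_types)
  if (any(unknown)) {
    warning(sum(unknown), " ClinVar record(s) with unknown Type counted as 'other'",
            call. = FALSE)
    type[unknown] <- "other"
  }
  type[type == "single nucleotide variant"] <- "snp"
  stars <- CLINVAR_STARS[tolower(df$ReviewStatus)]
  if (anyNA(stars)) {
    warning("unrecognised ClinVar review status mapped to 0 stars", call. = FALSE)
    stars[is.na(stars)] <- 0L
  }
  data.frame(
    rsid = ifelse(is.na(df[["RS#"]]) | df[["RS#"]] == "-1", df$Name,
                  paste0("rs", sub("^rs", "", df[["RS#"]]))),
    chrom = normalize_chrom(as.character(df$Chromosome)),
    start = as.numeric(df$Start) - 1, end = as.numeric(df$Stop),
    source = "clinvar",
    traits = df$PhenotypeList,
    p_value = NA_real_,
    variant_type = type,
    clinical_significance = df$ClinicalSignificance,
    review_stars = as.integer(stars),
    stringsAsFactors = FALSE
  )
}

#' Filter variants to CHD-associated records
#'
#' GWAS records are retained when any trait phrase contains a lexicon term
#' (case-insensitive substring after whitespace normalisation) AND the
#' association p-value is below `p_threshold`. ClinVar records are retained
#' on the trait match alone. The result is deduplicated by
#' (rsid, interval, source); on an rsid collision within a source the record
#' with the smallest p-value is kept.
#'
#' @param records variant data.frame ([read_gwas_catalog()]/[read_clinvar()]
#'   output, possibly rbind-ed).
#' @param lexicon character vector of lowercase trait phrases
#'   (default [chd_trait_lexicon()]).
#' @param p_threshold GWAS significance cutoff (exclusive); default `1e-5`.
#' @return filtered variant data.frame.
#' @export
filter_chd <- function(records, lexicon = chd_trait_lexicon(), p_threshold = 1e-5) {
  stopifnot(length(lexicon) > 0, p_threshold > 0, p_threshold < 1)
  if (nrow(records) == 0L) return(records)
  traits <- normalize_trait(records$traits)
  trait_hit <- Reduce(`|`, lapply(lexicon, function(term) {
    grepl(term, traits, fixed = TRUE)
  }))
  is_gwas <- records$source == "gwas"
  no_p <- is_gwas & is.na(records$p_value)
  if (any(no_p & trait_hit)) {
    warning(sum(no_p & trait_hit),
            " GWAS record(s) without a p-value excluded", call. = FALSE)
  }
  keep <- trait_hit & (!is_gwas | (!is.na(records$p_value) &
                                     records$p_value < p_threshold))
  out <- records[keep, , drop = FALSE]
  # smallest p first, then drop duplicate (rsid, interval, source)
  out <- out[order(out$rsid, out$source, out$p_value, na.last = TRUE), , drop = FALSE]
  key <- paste(out$rsid, out$chrom, out$start, out$end, out$source)
  out <- out[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tally variant types
#'
#' @param records variant data.frame with `variant_type`.
#' @return named integer vector over
#'   `snp, deletion, duplication, indel, insertion, microsatellite, other`.
#' @export
classify_variant_types <- function(records) {
  lvls <- c("snp", "deletion", "duplication", "indel", "insertion",
            "microsatellite", "other")
  type <- records$variant_type
  unknown <- !(type %in% lvls)
  if (any(unknown)) {
    warning(sum(unknown), " record(s) with unknown variant type counted as 'other'",
            call. = FALSE)
    type[unknown] <- "other"
  }
  table(factor(type, levels = lvls)) |> c()
}

#' Split annotated variants into coding and noncoding sets
#'
#' Coding means the exonic category; the noncoding set collects distal
#' intergenic, intronic, ncRNA-intronic and promoter variants. The split is
#' an exhaustive, disjoint partition.
#'
#' @param annotated variant data.frame with a `region_category` column
#'   (see [classify_location()]).
#' @return list with elements `coding` and `noncoding`.
#' @export
split_coding_noncoding <- function(annotated) {
  if (!"region_category" %in% names(annotated)) {
    stop("records lack a 'region_category' column; run classify_location() first",
         call. = FALSE)
  }
  noncoding_cats <- c("distal_intergenic", "intronic", "ncrna_intronic", "promoter")
  cat <- annotated$region_category
  if (anyNA(cat) || !all(cat %in% c("exonic", noncoding_cats))) {
    stop("uncategorised or unknown region category present", call. = FALSE)
  }
  list(coding = annotated[cat == "exonic", , drop = FALSE],
       noncoding = annotated[cat %in% noncoding_cats, , drop = FALSE])
}
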