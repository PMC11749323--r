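#' Controlled vocabularies and default thresholds
#'
#' The nine Carnegie stages with available human heart epigenomes, the three
#' enhancer-associated histone marks, the developmental stage groups used for
#' activity classification, and the cardiac tissues with eQTL tables.
#'
#' @name vocabularies
#' @keywords internal
NULL

#' @rdname vocabularies
#' @export
CARNEGIE_STAGES <- c("CS13", "CS14", "CS16", "CS17", "CS18",
                     "CS19", "CS20", "CS21", "CS23")

#' @rdname vocabularies
#' @export
HISTONE_MARKS <- c("H3K27ac", "H3K4me1", "H3K4me3")

#' @rdname vocabularies
#' @export
STAGE_GROUPS <- list(
  early        = c("CS13", "CS14", "CS16"),
  intermediate = c("CS17", "CS18", "CS19"),
  late         = c("CS20", "CS21", "CS23")
)

#' @rdname vocabularies
#' @export
CARDIAC_TISSUES <- c("Aorta", "Coronary_Artery",
                     "Heart_Atrial_Appendage", "Heart_Left_Ventricle")

# ClinVar review-status text -> star rating (standard ClinVar scheme).
CLINVAR_STARS <- c(
  "practice guideline" = 4L,
  "reviewed by expert panel" = 3L,
  "criteria provided, multiple submitters, no conflicts" = 2L,
  "criteria provided, conflicting interpretations" = 1L,
  "criteria provided, conflicting classifications" = 1L,
  "criteria provided, single submitter" = 1L,
  "no assertion criteria provided" = 0L,
  "no assertion provided" = 0L,
  "no classification provided" = 0L,
  "no classification for the single variant" = 0L
)

#' Default CHD trait lexicon
#'
#' Lowercase congenital-heart-disease trait phrases used for catalogue
#' filtering by case-insensitive substring match. The full curated lexicon in
#' the source study holds 56 phrases; the shipped default carries the core
#' phrases plus common CHD subtype names, and callers may extend it via
#' `extra_terms`.
#'
#' @param extra_terms character vector of additional phrases.
#' @return character vector of unique, lowercase, whitespace-normalised terms.
#' @export
chd_trait_lexicon <- function(extra_terms = character()) {
  base <- c(
    "congenital heart disease",
    "cardiac septal defects",
    "heart structural deformities",
    "non-syndromic chd",
    "chd subtypes",
    "atrial septal defect",
    "ventricular septal defect",
    "tetralogy of fallot",
    "patent ductus arteriosus",
    "hypoplastic left heart syndrome",
    "coarctation of the aorta",
    "transposition of the great arteries",
    "atrioventricular septal defect",
    "bicuspid aortic valve",
    "pulmonary valve stenosis",
    "congenital heart malformation",
    "conotruncal heart malformations"
  )
  terms <- unique(normalize_trait(c(base, extra_terms)))
  terms[nzchar(terms)]
}

# Lowercase and collapse runs of whitespace.
normalize_trait <- function(x) {
  gsub("\\s+", " ", trimws(tolower(x)))
}
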