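# Enumerated domains shared across the pipeline. Values are stored canonical
# upper-case; readers canonicalise case-insensitively.

.af_analysis_classes <- c(
  "GWAS_SNP", "GWAS_CNV", "WGS", "EXWAS", "RVAS",
  "TWAS", "EQTL_COLOC", "REPLICATION"
)

# classes whose reports are trait associations (trait must be set)
.af_association_classes <- c(
  "GWAS_SNP", "GWAS_CNV", "WGS", "EXWAS", "RVAS", "REPLICATION"
)

# classes carrying tissue-specific expression evidence (tissue must be set)
.af_expression_classes <- c("TWAS", "EQTL_COLOC")

.af_traits <- c("AF", "PR_INDICES", "LA_INDICES", "NONE")
.af_tissues <- c("LA", "RA", "LV", "NONE")
.af_annotation_sources <- c("V2G", "AUTHOR")
.af_indication_sources <- c("TRIAL", "ATC", "FDA_LABEL", "DAILYMED")

# evidence lattice: higher rank dominates
.af_level_rank <- c(
  GUIDELINE = 4L, SYSTEMATIC_REVIEW = 3L, RCT = 2L, OBSERVATIONAL = 1L,
  NONE = 0L
)

.af_effects <- c(
  "BENEFICIAL", "HARMFUL", "NEUTRAL", "MIXED", "POTENTIAL_HARM",
  "EXISTING_TREATMENT", "NONE"
)

# scoring domains
.af_score_traits <- c("AF", "PR_INDICES", "LA_INDICES")
.af_score_tissues <- c("LA", "RA", "LV")

# canonicalise a free-text enum value: trim, collapse inner whitespace to
# "_", upper-case ("Systematic review" -> "SYSTEMATIC_REVIEW")
canonical_enum <- function(x) {
  x <- gsub("[[:space:]]+", "_", trimws(x))
  toupper(x)
}

#' Evidence-level lattice
#'
#' The total order used to assign each drug its maximum level of evidence:
#' Guideline > Systematic Review > RCT > Observational (NONE below all).
#'
#' @return Named integer vector of level ranks, highest first.
#' @export
#' @examples
#' evidence_levels()
evidence_levels <- function() {
  sort(.af_level_rank, decreasing = TRUE)
}

# split a set-valued cell ("RA; LV" or "RA, LV") into a sorted unique vector
split_set <- function(x, sep = "[;,]") {
  if (length(x) != 1L) stop("split_set() expects a single string")
  if (is.na(x) || !nzchar(trimws(x))) return(character(0))
  parts <- trimws(strsplit(x, sep)[[1]])
  sort(unique(parts[nzchar(parts)]))
}

# inverse of split_set: canonical ";"-joined sorted set string
join_set <- function(x) paste(sort(unique(x[nzchar(x)])), collapse = ";")
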