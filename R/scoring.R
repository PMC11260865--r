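# Druggability and prioritisation scoring. All scores are additive indicator
# scores: one point per satisfied category, priority above a threshold
# (default > 1) in either druggability domain or in the multi-domain
# prioritisation score.

#' Small-molecule druggability score
#'
#' One point for membership in a druggable protein family and one point for
#' a usable binding pocket: a structure-based pocket score of at least 0.7
#' counts as a high-quality pocket and anything strictly between 0 and 0.7
#' as medium quality, both earning the single pocket point. A pocket score
#' of exactly 0 (no usable pocket) or a missing score earns nothing.
#'
#' @param druggable_family Logical vector: gene is in a druggable family.
#' @param pocket_score Numeric vector in `[0, 1]`, `NA` when no structure
#'   was assessed.
#' @return Integer vector of scores in 0..2.
#' @export
#' @examples
#' small_molecule_score(c(TRUE, TRUE, FALSE), c(0.9, 0, NA))
small_molecule_score <- function(druggable_family, pocket_score) {
  if (any(!is.na(pocket_score) & (pocket_score < 0 | pocket_score > 1))) {
    stop("validation error: pocket_score outside [0,1]", call. = FALSE)
  }
  as.integer(druggable_family) +
    as.integer(!is.na(pocket_score) & pocket_score > 0)
}

#' Antibody (biologic) accessibility score
#'
#' One point per source reporting high confidence that the protein sits in
#' an antibody-accessible compartment (plasma membrane, extracellular matrix
#' or secreted): UniProt, Gene Ontology and the Human Protein Atlas.
#'
#' @param accessible_uniprot,accessible_go,accessible_hpa Logical vectors.
#' @return Integer vector of scores in 0..3.
#' @export
#' @examples
#' antibody_score(TRUE, TRUE, FALSE)  # 2: priority under the > 1 rule
antibody_score <- function(accessible_uniprot, accessible_go,
                           accessible_hpa) {
  as.integer(accessible_uniprot) + as.integer(accessible_go) +
    as.integer(accessible_hpa)
}

#' Druggability scores for a tractability table
#'
#' Computes both domain scores per gene and flags druggability priority when
#' either domain exceeds the threshold.
#'
#' @param tractability Tractability frame
#'   (`read_table(..., "tractability")`).
#' @param threshold Priority cut-off; a domain score strictly greater than
#'   this flags priority (default 1).
#' @return Data frame: `ensembl_id`, `sm_score`, `ab_score`,
#'   `druggability_priority`.
#' @export
druggability_scores <- function(tractability, threshold = 1) {
  out <- data.frame(
    ensembl_id = tractability$ensembl_id,
    sm_score = small_molecule_score(tractability$druggable_family,
                                    tractability$pocket_score),
    ab_score = antibody_score(tractability$accessible_uniprot,
                              tractability$accessible_go,
                              tractability$accessible_hpa),
    stringsAsFactors = FALSE
  )
  out$druggability_priority <- out$sm_score > threshold |
    out$ab_score > threshold
  out
}

#' Multi-domain prioritisation score for gene evidence profiles
#'
#' One point per trait (AF, PR indices, LA indices) with at least one
#' genetic association report, one point per cardiac tissue (LA, RA, LV)
#' with at least one TWAS or eQTL-colocalization report, and one point for
#' rare-variant (RVAS) support; multiple studies of the same trait or tissue
#' contribute once. Genes whose total exceeds the threshold are flagged as
#' priority targets.
#'
#' @param profiles Per-gene profiles from [collapse_reports()] (columns
#'   `symbol`, `traits`, `tissues`, `rvas`).
#' @param threshold Priority cut-off; total strictly greater flags priority
#'   (default 1).
#' @return Data frame: `symbol`, `trait_points` (0..3), `tissue_points`
#'   (0..3), `rvas_point` (0..1), `prioritisation_score` (0..7),
#'   `gene_priority`.
#' @export
prioritisation_score <- function(profiles, threshold = 1) {
  trait_points <- vapply(profiles$traits, function(x) {
    length(intersect(split_set(x), .af_score_traits))
  }, integer(1), USE.NAMES = FALSE)
  tissue_points <- vapply(profiles$tissues, function(x) {
    length(intersect(split_set(x), .af_score_tissues))
  }, integer(1), USE.NAMES = FALSE)
  rvas_point <- as.integer(as.logical(profiles$rvas))
  total <- trait_points + tissue_points + rvas_point
  data.frame(symbol = profiles$symbol, trait_points = trait_points,
             tissue_points = tissue_points, rvas_point = rvas_point,
             prioritisation_score = total, gene_priority = total > threshold,
             stringsAsFactors = FALSE)
}

#' Score targets across both druggability domains and the gene domain
#'
#' Joins [prioritisation_score()] on the evidence profiles with
#' [druggability_scores()] on the tractability table. Genes without a
#' tractability record score 0 in both druggability domains.
#'
#' @param profiles Per-gene profiles from [collapse_reports()]; an
#'   `ensembl_id` column, if present, is used for the tractability join,
#'   otherwise `symbol` is matched against `tractability$ensembl_id`.
#' @param tractability Tractability frame, or `NULL` to skip druggability.
#' @param gene_threshold,druggability_threshold Priority cut-offs (default 1).
#' @return One row per gene with all score components and both priority
#'   flags.
#' @export
score_targets <- function(profiles, tractability = NULL, gene_threshold = 1,
                          druggability_threshold = 1) {
  out <- prioritisation_score(profiles, threshold = gene_threshold)
  if ("ensembl_id" %in% names(profiles)) {
    out$ensembl_id <- profiles$ensembl_id
  } else {
    out$ensembl_id <- profiles$symbol
  }
  if (!is.null(tractability)) {
    dr <- druggability_scores(tractability,
                              threshold = druggability_threshold)
    idx <- match(out$ensembl_id, dr$ensembl_id)
    out$sm_score <- ifelse(is.na(idx), 0L, dr$sm_score[idx])
    out$ab_score <- ifelse(is.na(idx), 0L, dr$ab_score[idx])
    out$druggability_priority <- !is.na(idx) & dr$druggability_priority[idx]
  } else {
    out$sm_score <- 0L
    out$ab_score <- 0L
    out$druggability_priority <- FALSE
  }
  out
}

#' Rank targets by prioritisation score
#'
#' Orders descending by prioritisation score with a deterministic
#' alphabetical tie-break on the gene symbol, so the ranking is invariant
#' under permutation of the input.
#'
#' @param scores Frame from [prioritisation_score()] or [score_targets()].
#' @return The same frame, reordered.
#' @export
rank_targets <- function(scores) {
  out <- scores[order(-scores$prioritisation_score, scores$symbol), ,
                drop = FALSE]
  rownames(out) <- NULL
  out
}
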