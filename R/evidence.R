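# Clinical-evidence synthesis: reduce curated per-drug evidence items to a
# per-drug summary with a maximum level of evidence under the lattice
# Guideline > Systematic Review > RCT > Observational, a reconciled overall
# effect, and a priority flag propagated from the target scores.

#' Maximum evidence level of a set of items
#'
#' The supremum of the design levels under the evidence lattice
#' Guideline > Systematic Review > RCT > Observational; `NONE` for an empty
#' set. As a fold over a total order this is associative and commutative,
#' and adding an item can never lower the result.
#'
#' @param levels Character vector of design levels (`GUIDELINE`,
#'   `SYSTEMATIC_REVIEW`, `RCT`, `OBSERVATIONAL`), e.g. the `design_level`
#'   column of an evidence-item frame.
#' @return A single level string.
#' @export
#' @examples
#' max_evidence_level(c("RCT", "SYSTEMATIC_REVIEW"))
max_evidence_level <- function(levels) {
  levels <- canonical_enum(levels)
  bad <- setdiff(levels, names(.af_level_rank))
  if (length(bad)) {
    stop("unknown evidence level(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!length(levels)) return("NONE")
  names(which.max(.af_level_rank[levels]))
}

#' Reconcile the overall effect of evidence items
#'
#' A drug on an AF-management guideline is labelled `EXISTING_TREATMENT`
#' regardless of its items. Otherwise effects are reconciled among the items
#' at the maximum evidence level only (lower-level contradictions do not
#' dilute the top level): a unanimous direction is kept; both beneficial and
#' harmful present gives `MIXED`; harm supported only by observational data
#' is downgraded to `POTENTIAL_HARM`; otherwise harm dominates benefit
#' dominates mixed dominates neutral.
#'
#' @param items Evidence-item frame (columns `design_level`, `effect`), or
#'   `NULL`/empty for no evidence.
#' @param max_level Maximum level to reconcile at; computed from the items
#'   when `NULL`.
#' @param guideline_flag Is the drug in an AF-management guideline?
#' @return A single effect string (`NONE` when there is nothing to
#'   reconcile).
#' @export
#' @examples
#' items <- data.frame(design_level = c("RCT", "RCT"),
#'                     effect = c("BENEFICIAL", "HARMFUL"))
#' overall_effect(items)                      # MIXED
#' overall_effect(items, guideline_flag = TRUE)  # EXISTING_TREATMENT
overall_effect <- function(items, max_level = NULL, guideline_flag = FALSE) {
  if (isTRUE(guideline_flag)) return("EXISTING_TREATMENT")
  if (is.null(items) || !nrow(items)) return("NONE")
  lv <- canonical_enum(items$design_level)
  if (is.null(max_level)) max_level <- max_evidence_level(lv)
  eff <- canonical_enum(items$effect[lv == max_level])
  if (!length(eff)) return("NONE")
  # fold POTENTIAL_HARM into the harm direction for reconciliation
  dir <- unique(ifelse(eff == "POTENTIAL_HARM", "HARMFUL", eff))
  if (length(dir) == 1L && dir != "HARMFUL") return(dir)
  harmful <- "HARMFUL" %in% dir
  beneficial <- "BENEFICIAL" %in% dir
  if (harmful && beneficial) return("MIXED")
  if (harmful) {
    if (max_level == "OBSERVATIONAL") return("POTENTIAL_HARM")
    return("HARMFUL")
  }
  if (beneficial) return("BENEFICIAL")
  if ("MIXED" %in% dir) return("MIXED")
  "NEUTRAL"
}

#' Assemble the per-drug evidence summary
#'
#' Reduces curated evidence items to one summary row per parent drug with at
#' least one item: the associated target symbols, the maximum evidence
#' level, the reconciled overall effect (guideline drugs become existing
#' treatments), safety annotations pooled over the member formulations, and
#' a high-priority flag that is true exactly when some associated target has
#' gene priority. Drugs with no items are excluded from the summary but
#' counted in the `"coverage"` attribute.
#'
#' @param parents Parent-drug frame from [deduplicate_drugs()].
#' @param links Drug-target links from [join_targets_to_drugs()].
#' @param scores Target scores from [score_targets()] or
#'   [prioritisation_score()] (columns `symbol`, `gene_priority`).
#' @param items Evidence-item frame (`read_table(..., "evidence_item")`);
#'   `drug_name` must match a parent key (case-insensitively). An item
#'   naming an unknown drug is a dangling-reference error.
#' @param guideline_list Character vector of parent drugs included in AF
#'   management guidelines.
#' @param drugs Optional drug frame supplying `black_box` and `withdrawn`
#'   for the member formulations.
#' @return Data frame: `drug_name`, `associated_targets` (";"-joined),
#'   `max_level`, `overall_effect`, `black_box`, `withdrawn`,
#'   `high_priority`; attribute `"coverage"` records drugs with/without
#'   evidence.
#' @export
assemble_summary <- function(parents, links, scores, items, guideline_list,
                             drugs = NULL) {
  key <- .af_norm_name(parents$parent_drug_key)
  item_key <- .af_norm_name(items$drug_name)
  dangling <- setdiff(unique(item_key), key)
  if (length(dangling)) {
    stop("dangling-reference error: evidence item(s) for unknown drug(s): ",
         paste(dangling, collapse = ", "), call. = FALSE)
  }
  guideline <- .af_norm_name(guideline_list)
  rows <- lapply(which(key %in% item_key), function(i) {
    k <- key[i]
    member_ids <- strsplit(parents$member_ids[i], ";", fixed = TRUE)[[1]]
    syms <- sort(unique(links$hgnc_symbol[links$drug_id %in% member_ids]))
    it <- items[item_key == k, , drop = FALSE]
    lvl <- max_evidence_level(it$design_level)
    in_guideline <- k %in% guideline
    eff <- overall_effect(it, max_level = lvl,
                          guideline_flag = in_guideline)
    if (in_guideline) lvl <- "GUIDELINE"
    black_box <- ""
    withdrawn <- FALSE
    if (!is.null(drugs)) {
      d <- drugs[drugs$drug_id %in% member_ids, , drop = FALSE]
      bb <- unique(trimws(d$black_box))
      black_box <- paste(bb[nzchar(bb)], collapse = "; ")
      withdrawn <- any(d$withdrawn)
    }
    data.frame(drug_name = parents$parent_drug_key[i],
               associated_targets = paste(syms, collapse = ";"),
               max_level = lvl, overall_effect = eff,
               black_box = black_box, withdrawn = withdrawn,
               high_priority = any(scores$gene_priority[
                 scores$symbol %in% syms]),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(drug_name = character(0), associated_targets = character(0),
               max_level = character(0), overall_effect = character(0),
               black_box = character(0), withdrawn = logical(0),
               high_priority = logical(0), stringsAsFactors = FALSE)
  out <- out[order(out$drug_name), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "coverage") <- list(
    n_parents = nrow(parents),
    n_with_evidence = nrow(out),
    n_without_evidence = nrow(parents) - nrow(out)
  )
  out
}
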