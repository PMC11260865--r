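# Drug cross-referencing: joining targets to drugs through mechanism-of-
# action records, collapsing salt/ester formulations to parent drugs,
# decoding ontology-coded indications, and constructing the literature
# search query strings.

#' Join targets to drugs through mechanism records
#'
#' Produces one drug-target link per mechanism row whose target appears in
#' the supplied target set, carrying the action type and target class.
#' Targets with no mechanism rows are reported separately (attribute
#' `"undrugged"`) as druggable-but-undrugged candidates. A mechanism
#' referencing a drug id absent from the drug table is a dangling-reference
#' error.
#'
#' @param targets Frame with columns `ensembl_id`, `hgnc_symbol` and
#'   optionally `target_class` (e.g. the target registry restricted to
#'   genes of interest).
#' @param mechanisms Mechanism frame (`read_table(..., "mechanism")`).
#' @param drugs Drug frame (`read_table(..., "drug")`).
#' @return Data frame of links: `drug_id`, `drug_name`, `ensembl_id`,
#'   `hgnc_symbol`, `action_type`, `target_class`; attribute `"undrugged"`
#'   holds the zero-link targets.
#' @export
join_targets_to_drugs <- function(targets, mechanisms, drugs) {
  dangling <- setdiff(unique(mechanisms$drug_id), drugs$drug_id)
  if (length(dangling)) {
    stop("dangling-reference error: mechanism drug id(s) not in drug table: ",
         paste(dangling, collapse = ", "), call. = FALSE)
  }
  keep <- mechanisms$target_ensembl_id %in% targets$ensembl_id
  mech <- mechanisms[keep, , drop = FALSE]
  tidx <- match(mech$target_ensembl_id, targets$ensembl_id)
  didx <- match(mech$drug_id, drugs$drug_id)
  links <- data.frame(
    drug_id = mech$drug_id,
    drug_name = drugs$name[didx],
    ensembl_id = mech$target_ensembl_id,
    hgnc_symbol = targets$hgnc_symbol[tidx],
    action_type = mech$action_type,
    target_class = if ("target_class" %in% names(targets))
      targets$target_class[tidx] else "",
    stringsAsFactors = FALSE
  )
  links <- unique(links)
  links <- links[order(links$drug_id, links$ensembl_id, links$action_type), ,
                 drop = FALSE]
  rownames(links) <- NULL
  undrugged <- targets[!targets$ensembl_id %in% links$ensembl_id, ,
                       drop = FALSE]
  attr(links, "undrugged") <- undrugged
  links
}

# normalise a drug name for dedup: case-fold, trim, collapse whitespace
.af_norm_name <- function(x) {
  tolower(gsub("[[:space:]]+", " ", trimws(x)))
}

#' Parent-drug key for a drug name
#'
#' Strips trailing salt/ester/counter-ion tokens (from the salt lexicon,
#' applied repeatedly) from the case-folded name. Names on the conjugate
#' whitelist — conjugates of two active moieties, as with some
#' antibody-drug conjugates — are kept verbatim as their own parent.
#'
#' @param name Character vector of drug names.
#' @param salt_lexicon Character vector of salt tokens; defaults to the
#'   packaged lexicon.
#' @param conjugate_whitelist Character vector of active-moiety conjugate
#'   names kept distinct; defaults to the packaged list.
#' @return Character vector of parent keys (normalised names).
#' @export
#' @examples
#' parent_drug_key(c("Metoprolol Tartrate", "metoprolol succinate"))
parent_drug_key <- function(name,
                            salt_lexicon = load_fixture("SALT_LEXICON"),
                            conjugate_whitelist =
                              load_fixture("CONJUGATE_WHITELIST")) {
  norm <- .af_norm_name(name)
  lex <- .af_norm_name(salt_lexicon)
  wl <- .af_norm_name(conjugate_whitelist)
  vapply(norm, function(n) {
    if (n %in% wl) return(n)
    repeat {
      words <- strsplit(n, " ", fixed = TRUE)[[1]]
      if (length(words) < 2L || !words[length(words)] %in% lex) break
      n <- paste(words[-length(words)], collapse = " ")
    }
    n
  }, character(1), USE.NAMES = FALSE)
}

#' Deduplicate drug formulations to parent drugs
#'
#' Groups drug records whose names differ only by salt formulation or
#' pharmacokinetic conjugation under one parent drug, while conjugates of
#' two active compounds (whitelisted) remain unique. The grouping is a
#' partition of the input, idempotent and order-invariant.
#'
#' @param drugs Drug frame (`read_table(..., "drug")`, columns `drug_id`,
#'   `name` required).
#' @inheritParams parent_drug_key
#' @return Data frame with one row per parent, sorted by key:
#'   `parent_drug_key`, `n_members`, `member_ids` and `member_names`
#'   (";"-joined); attribute `"membership"` maps every input `drug_id` to
#'   its `parent_drug_key`.
#' @export
deduplicate_drugs <- function(drugs,
                              salt_lexicon = load_fixture("SALT_LEXICON"),
                              conjugate_whitelist =
                                load_fixture("CONJUGATE_WHITELIST")) {
  key <- parent_drug_key(drugs$name, salt_lexicon, conjugate_whitelist)
  membership <- data.frame(drug_id = drugs$drug_id, name = drugs$name,
                           parent_drug_key = key, stringsAsFactors = FALSE)
  membership <- membership[order(membership$parent_drug_key,
                                 membership$drug_id), , drop = FALSE]
  rownames(membership) <- NULL
  by_parent <- split(membership, membership$parent_drug_key)
  parents <- do.call(rbind, lapply(by_parent, function(g) {
    data.frame(parent_drug_key = g$parent_drug_key[1],
               n_members = nrow(g),
               member_ids = paste(g$drug_id, collapse = ";"),
               member_names = paste(g$name, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  rownames(parents) <- NULL
  attr(parents, "membership") <- membership
  parents
}

#' Decode ontology-coded indications into specialty categories
#'
#' Maps each indication's ontology term to a clinical-specialty category
#' through a flat term-to-label mapping table, after removing rows sourced
#' from DailyMed (whose coding is unreliable and is excluded downstream).
#' Unmapped terms are never dropped silently: they are retained with
#' specialty `UNMAPPED` and listed in the `"unmapped"` attribute.
#'
#' @param indications Indication frame (`read_table(..., "indication")`).
#' @param ontology_map Frame with columns `ontology_term`, `specialty` and
#'   optionally `secondary` and `decoded_label`.
#' @return The decoded indication frame (DailyMed rows removed), with
#'   attribute `"unmapped"` holding the unmapped term ids.
#' @export
decode_indications <- function(indications, ontology_map) {
  out <- indications[indications$evidence_source != "DAILYMED", ,
                     drop = FALSE]
  idx <- match(out$ontology_term, ontology_map$ontology_term)
  out$specialty <- ifelse(is.na(idx), "UNMAPPED",
                          ontology_map$specialty[idx])
  if ("secondary" %in% names(ontology_map)) {
    out$secondary <- ifelse(is.na(idx), "", ontology_map$secondary[idx])
  }
  if ("decoded_label" %in% names(ontology_map)) {
    out$decoded_label <- ifelse(is.na(idx), out$decoded_label,
                                ontology_map$decoded_label[idx])
  }
  rownames(out) <- NULL
  attr(out, "unmapped") <- unique(out$ontology_term[is.na(idx)])
  out
}

#' Build literature-review query strings for drugs
#'
#' For each parent drug, constructs the two structured searches used for
#' clinical-evidence review: a MEDLINE boolean query `"<drug>" AND
#' "<condition>"` and a trial-registry query as a (condition, intervention)
#' pair. One query record per drug and source, deduplicated, so the record
#' count is twice the number of distinct drugs.
#'
#' @param drug_name Character vector of (parent) drug names.
#' @param condition Condition string (default `"atrial fibrillation"`).
#' @return Data frame: `drug_name`, `source` (`MEDLINE` / `REGISTRY`),
#'   `query`, `condition`, `intervention`.
#' @export
#' @examples
#' build_search_queries("ranolazine")$query[1]
build_search_queries <- function(drug_name,
                                 condition = "atrial fibrillation") {
  drug_name <- unique(trimws(drug_name))
  if (!length(drug_name) || any(!nzchar(drug_name))) {
    stop("drug_name must be non-empty", call. = FALSE)
  }
  medline <- data.frame(
    drug_name = drug_name, source = "MEDLINE",
    query = sprintf('"%s" AND "%s"', drug_name, condition),
    condition = condition, intervention = drug_name,
    stringsAsFactors = FALSE
  )
  registry <- data.frame(
    drug_name = drug_name, source = "REGISTRY",
    query = sprintf("condition=%s; intervention=%s", condition, drug_name),
    condition = condition, intervention = drug_name,
    stringsAsFactors = FALSE
  )
  out <- rbind(medline, registry)
  out <- out[order(out$drug_name, out$source), , drop = FALSE]
  rownames(out) <- NULL
  out
}
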