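# Summary structures: the indication co-occurrence adjacency matrix behind
# the chord diagram, the action-type dendrogram for high-priority drugs, and
# the drugged-target partition by trait combination.

#' Indication co-occurrence adjacency matrix
#'
#' Builds the square symmetric matrix behind the indication chord diagram:
#' entry (i, j) counts the parent drugs indicated for both specialty i and
#' specialty j, and the diagonal (i, i) counts the drugs with specialty i.
#' Counting is at drug granularity (an indication category contributes once
#' per drug however many trials record it). Categories are ordered by
#' descending diagonal count, ties alphabetical.
#'
#' @param indications Decoded indication frame from [decode_indications()]
#'   (columns `drug_id`, `specialty`).
#' @param membership Optional membership frame (from
#'   `attr(deduplicate_drugs(...), "membership")`) mapping `drug_id` to
#'   `parent_drug_key`; when supplied, co-occurrence is counted per parent
#'   drug rather than per formulation.
#' @return An `"indication_adjacency"` object: list with `categories` and
#'   the integer `matrix` (0 x 0 for empty input).
#' @export
#' @examples
#' ind <- data.frame(drug_id = c("a", "b", "b"),
#'                   specialty = c("CARDIOLOGY", "CARDIOLOGY", "RESPIRATORY"),
#'                   evidence_source = "TRIAL")
#' indication_adjacency(ind)$matrix
indication_adjacency <- function(indications, membership = NULL) {
  drug <- indications$drug_id
  if (!is.null(membership)) {
    idx <- match(drug, membership$drug_id)
    drug <- ifelse(is.na(idx), drug, membership$parent_drug_key[idx])
  }
  keep <- nzchar(indications$specialty)
  sets <- lapply(split(indications$specialty[keep], drug[keep]), unique)
  cats <- sort(unique(unlist(sets)))
  if (!length(cats)) {
    out <- list(categories = character(0),
                matrix = matrix(0L, 0, 0))
    class(out) <- "indication_adjacency"
    return(out)
  }
  m <- matrix(0L, length(cats), length(cats), dimnames = list(cats, cats))
  for (s in sets) {
    for (i in s) for (j in s) m[i, j] <- m[i, j] + 1L
  }
  ord <- order(-diag(m), cats)
  m <- m[ord, ord, drop = FALSE]
  out <- list(categories = rownames(m), matrix = m)
  class(out) <- "indication_adjacency"
  out
}

#' @export
print.indication_adjacency <- function(x, ...) {
  cat(sprintf("Indication co-occurrence matrix: %d categories\n",
              length(x$categories)))
  if (length(x$categories)) print(x$matrix)
  invisible(x)
}

#' @export
as.matrix.indication_adjacency <- function(x, ...) x$matrix

#' Action-type dendrogram for high-priority drugs
#'
#' Builds the tree behind the drug-action dendrogram, restricted to drugs
#' whose linked targets include at least one with gene priority: root →
#' action type → target class → target → drug leaves. Each (drug, target,
#' action) link of a high-priority drug contributes one leaf.
#'
#' @param links Drug-target links from [join_targets_to_drugs()].
#' @param scores Target scores (columns `symbol`, `gene_priority`).
#' @return An `"action_tree"` object: nested list (`children` at each
#'   level) with attributes in `$leaf_counts` (per action type),
#'   `$n_leaves`, and `$inhibitor_share` (fraction of leaves whose action
#'   type is inhibitor; `NA` when there are no leaves).
#' @export
action_dendrogram <- function(links, scores) {
  priority_syms <- scores$symbol[scores$gene_priority]
  priority_drugs <- unique(links$drug_id[links$hgnc_symbol %in%
                                           priority_syms])
  lk <- links[links$drug_id %in% priority_drugs, , drop = FALSE]
  lk <- unique(lk[c("drug_id", "drug_name", "hgnc_symbol", "action_type",
                    "target_class")])
  action <- canonical_enum(lk$action_type)
  children <- list()
  if (nrow(lk)) {
    for (a in sort(unique(action))) {
      la <- lk[action == a, , drop = FALSE]
      classes <- list()
      for (cl in sort(unique(la$target_class))) {
        lc <- la[la$target_class == cl, , drop = FALSE]
        targets <- list()
        for (sym in sort(unique(lc$hgnc_symbol))) {
          leaves <- sort(unique(lc$drug_name[lc$hgnc_symbol == sym]))
          targets[[sym]] <- list(name = sym, drugs = leaves)
        }
        classes[[cl]] <- list(name = cl, children = targets)
      }
      children[[a]] <- list(name = a, children = classes)
    }
  }
  leaf_counts <- if (nrow(lk)) table(action) else table(character(0))
  n_leaves <- nrow(lk)
  inhibitor <- sum(action %in% c("INHIBITOR", "INHIBITORS"))
  out <- list(
    name = "drugs", children = children,
    leaf_counts = as.integer(leaf_counts),
    n_leaves = n_leaves,
    inhibitor_share = if (n_leaves) inhibitor / n_leaves else NA_real_
  )
  names(out$leaf_counts) <- names(leaf_counts)
  class(out) <- "action_tree"
  out
}

#' @export
print.action_tree <- function(x, ...) {
  cat(sprintf("Drug-action tree: %d leaves over %d action types\n",
              x$n_leaves, length(x$children)))
  for (nm in names(x$leaf_counts)) {
    cat(sprintf("  %s: %d\n", nm, x$leaf_counts[[nm]]))
  }
  invisible(x)
}

#' Serialise an action tree
#'
#' `tree_to_json()` emits the nested structure as JSON;
#' `tree_to_newick()` emits a Newick-like text form of the dendrogram
#' (drug leaves, inner labels for targets, classes and action types).
#'
#' @param tree An `"action_tree"` object.
#' @return A JSON string / a Newick string.
#' @export
tree_to_json <- function(tree) {
  jsonlite::toJSON(unclass(tree), auto_unbox = TRUE, pretty = TRUE)
}

#' @rdname tree_to_json
#' @export
tree_to_newick <- function(tree) {
  esc <- function(x) gsub("[():;, ]", "_", x)
  act <- vapply(tree$children, function(a) {
    cls <- vapply(a$children, function(cl) {
      tg <- vapply(cl$children, function(t) {
        sprintf("(%s)%s", paste(esc(t$drugs), collapse = ","), esc(t$name))
      }, character(1))
      sprintf("(%s)%s", paste(tg, collapse = ","), esc(cl$name))
    }, character(1))
    sprintf("(%s)%s", paste(cls, collapse = ","), esc(a$name))
  }, character(1))
  if (!length(act)) return("();")
  sprintf("(%s)%s;", paste(act, collapse = ","), esc(tree$name))
}

#' Partition drugged targets by trait combination
#'
#' Exhaustive mutually-exclusive counts of drugged targets over the seven
#' non-empty combinations of the scored traits (AF, PR indices, LA indices),
#' plus a `NONE` cell for drugged targets with no trait association, so the
#' cells always sum exactly to the number of drugged targets.
#'
#' @param profiles Per-gene profiles from [collapse_reports()] (columns
#'   `symbol`, `traits`).
#' @param links Drug-target links; only targets appearing in `links` are
#'   counted. Pass `NULL` to partition all profiles.
#' @return Named integer vector over the 8 cells (`AF`, `PR_INDICES`,
#'   `LA_INDICES`, `AF+PR_INDICES`, `AF+LA_INDICES`,
#'   `PR_INDICES+LA_INDICES`, `AF+PR_INDICES+LA_INDICES`, `NONE`).
#' @export
partition_by_trait <- function(profiles, links = NULL) {
  if (!is.null(links)) {
    profiles <- profiles[profiles$symbol %in% links$hgnc_symbol, ,
                         drop = FALSE]
  }
  combos <- c("AF", "PR_INDICES", "LA_INDICES", "AF+PR_INDICES",
              "AF+LA_INDICES", "PR_INDICES+LA_INDICES",
              "AF+PR_INDICES+LA_INDICES", "NONE")
  cells <- setNames(integer(length(combos)), combos)
  for (tr in profiles$traits) {
    s <- intersect(split_set(tr), .af_score_traits)
    lab <- if (!length(s)) "NONE" else
      paste(.af_score_traits[.af_score_traits %in% s], collapse = "+")
    cells[lab] <- cells[lab] + 1L
  }
  cells
}
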