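# Gene harmonisation: resolving reported gene labels against the target
# registry and applying the variant-to-gene annotation fallback chain.

#' Normalise a gene symbol
#'
#' Trims whitespace, case-folds to upper case and strips a trailing
#' ".<digits>" version suffix, so that the variously-cased symbols found in
#' published tables compare equal.
#'
#' @param x Character vector of reported symbols.
#' @return Normalised character vector.
#' @export
#' @examples
#' normalise_symbol(c(" scn5a ", "KCNJ5.2"))
normalise_symbol <- function(x) {
  sub("\\.[0-9]+$", "", toupper(trimws(x)))
}

# build a synonym lookup: normalised synonym -> registry row indices
.af_synonym_index <- function(registry) {
  syn <- lapply(registry$synonyms, split_set)
  idx <- rep(seq_len(nrow(registry)), lengths(syn))
  data.frame(synonym = normalise_symbol(unlist(syn)), row = idx,
             stringsAsFactors = FALSE)
}

#' Resolve a reported gene symbol against the target registry
#'
#' Applies the fallback chain used when published gene labels do not match
#' approved nomenclature: exact match on the registry symbol, then a
#' synonym match in the registry, then an explicit manual mapping; a symbol
#' surviving all three stages is unresolved. A synonym matching two distinct
#' registry entries is an ambiguity error (such symbols are logged rather
#' than guessed by the vectorised wrapper).
#'
#' @param reported A single reported symbol.
#' @param registry Target registry frame (`read_table(..., "target_registry")`):
#'   columns `ensembl_id`, `hgnc_symbol`, `synonyms` (";"-joined).
#' @param manual_map Optional frame with columns `reported_symbol`,
#'   `hgnc_symbol`, `ensembl_id` modelling manually curated web-search
#'   resolutions.
#' @return A one-row data frame: `reported_symbol`, `resolved_symbol`,
#'   `ensembl_id`, `method` (`EXACT`, `SYNONYM`, `MANUAL` or `UNRESOLVED`;
#'   unresolved rows have empty symbol and id).
#' @seealso [resolve_symbols()] for the vectorised, logging variant.
#' @export
resolve_symbol <- function(reported, registry, manual_map = NULL) {
  stopifnot(length(reported) == 1L)
  norm <- normalise_symbol(reported)
  res <- function(symbol, id, method) {
    data.frame(reported_symbol = reported, resolved_symbol = symbol,
               ensembl_id = id, method = method, stringsAsFactors = FALSE)
  }
  hit <- which(normalise_symbol(registry$hgnc_symbol) == norm)
  if (length(hit) >= 1L) {
    return(res(registry$hgnc_symbol[hit[1]], registry$ensembl_id[hit[1]],
               "EXACT"))
  }
  syn <- .af_synonym_index(registry)
  rows <- unique(syn$row[syn$synonym == norm])
  if (length(rows) > 1L) {
    cand <- registry$hgnc_symbol[rows]
    cond <- structure(
      class = c("aftargets_ambiguity", "error", "condition"),
      list(message = sprintf(
        "ambiguity error: '%s' matches synonyms of %d registry entries: %s",
        reported, length(cand), paste(cand, collapse = ", ")),
        call = sys.call(-1), candidates = cand))
    stop(cond)
  }
  if (length(rows) == 1L) {
    return(res(registry$hgnc_symbol[rows], registry$ensembl_id[rows],
               "SYNONYM"))
  }
  if (!is.null(manual_map) && nrow(manual_map)) {
    m <- which(normalise_symbol(manual_map$reported_symbol) == norm)
    if (length(m) >= 1L) {
      return(res(manual_map$hgnc_symbol[m[1]], manual_map$ensembl_id[m[1]],
                 "MANUAL"))
    }
  }
  res("", "", "UNRESOLVED")
}

#' Resolve many reported symbols, logging ambiguities
#'
#' Vectorised [resolve_symbol()]. Ambiguous synonym hits are not guessed:
#' they are marked `UNRESOLVED` and recorded (with their candidate entries)
#' in the `"ambiguities"` attribute, alongside an `"unresolved"` attribute
#' listing symbols no stage could place.
#'
#' @inheritParams resolve_symbol
#' @param reported Character vector of reported symbols.
#' @return Data frame with one row per input symbol (same columns as
#'   [resolve_symbol()]), with attributes `"unresolved"` and `"ambiguities"`.
#' @export
resolve_symbols <- function(reported, registry, manual_map = NULL) {
  ambiguities <- list()
  rows <- lapply(reported, function(r) {
    tryCatch(resolve_symbol(r, registry, manual_map),
             aftargets_ambiguity = function(e) {
               ambiguities[[r]] <<- e$candidates
               data.frame(reported_symbol = r, resolved_symbol = "",
                          ensembl_id = "", method = "UNRESOLVED",
                          stringsAsFactors = FALSE)
             })
  })
  out <- do.call(rbind, rows)
  attr(out, "unresolved") <-
    unique(out$reported_symbol[out$method == "UNRESOLVED"])
  attr(out, "ambiguities") <- ambiguities
  out
}

#' Annotate one variant through the variant-to-gene table
#'
#' Returns the variant-to-gene assignment when the variant is present (with
#' a non-empty gene) in the lookup table, and otherwise falls back to the
#' original authors' annotation. A variant present with an empty gene is
#' treated as absent.
#'
#' @param variant_id Variant identifier (opaque key, e.g. an rsID).
#' @param v2g Variant-to-gene frame with columns `variant_id`, `gene`.
#' @param author_gene The original authors' gene annotation for the report.
#' @return A one-row data frame: `gene`, `annotation_source` (`"V2G"` or
#'   `"AUTHOR"`).
#' @export
#' @examples
#' v2g <- data.frame(variant_id = "rs1", gene = "SCN5A")
#' annotate_variant("rs1", v2g, "KCNJ5")  # V2G wins
#' annotate_variant("rs9", v2g, "KCNJ5")  # falls back to AUTHOR
annotate_variant <- function(variant_id, v2g, author_gene) {
  stopifnot(length(variant_id) == 1L, length(author_gene) == 1L)
  hit <- which(v2g$variant_id == variant_id & nzchar(trimws(v2g$gene)))
  if (nzchar(trimws(variant_id)) && length(hit) >= 1L) {
    data.frame(gene = v2g$gene[hit[1]], annotation_source = "V2G",
               stringsAsFactors = FALSE)
  } else {
    data.frame(gene = author_gene, annotation_source = "AUTHOR",
               stringsAsFactors = FALSE)
  }
}

#' Annotate gene reports through the variant-to-gene chain
#'
#' Applies [annotate_variant()] to every report: reports whose variant is in
#' the lookup table take the variant-to-gene assignment (source `V2G`),
#' the rest keep the authors' reported symbol (source `AUTHOR`). Reports
#' without a variant (e.g. TWAS gene-level reports) always keep the author
#' annotation.
#'
#' @param reports Gene-report frame (`read_table(..., "gene_report")`).
#' @param v2g Variant-to-gene frame with columns `variant_id`, `gene`.
#' @return `reports` with `reported_symbol` and `annotation_source` updated.
#' @export
annotate_variants <- function(reports, v2g) {
  if (!nrow(reports)) return(reports)
  lut <- v2g[nzchar(trimws(v2g$gene)), , drop = FALSE]
  lut <- lut[!duplicated(lut$variant_id), , drop = FALSE]
  idx <- match(reports$variant_id, lut$variant_id)
  hit <- !is.na(idx) & nzchar(trimws(reports$variant_id))
  reports$reported_symbol[hit] <- lut$gene[idx[hit]]
  reports$annotation_source <- ifelse(hit, "V2G", "AUTHOR")
  reports
}

#' Collapse per-study gene reports to per-gene evidence profiles
#'
#' Builds one profile per resolved gene: the set of traits with at least one
#' association report, the set of cardiac tissues with at least one TWAS or
#' eQTL-colocalization report (TWAS and eQTL evidence in the same tissue is
#' counted once), a rare-variant flag (any RVAS report) and per-analysis-class
#' report counts. Identical duplicate reports are collapsed first, so the
#' output is invariant under permutation and duplication of the input.
#'
#' @param reports Gene-report frame whose `reported_symbol` column already
#'   carries resolved symbols (see [resolve_symbols()]).
#' @return Data frame sorted by symbol: `symbol`, `traits` and `tissues`
#'   (";"-joined sorted sets), `rvas` (logical), one `n_<class>` count per
#'   analysis class, and `n_reports` (distinct reports).
#' @export
collapse_reports <- function(reports) {
  cols <- c("study_id", "analysis_class", "trait", "tissue", "variant_id",
            "reported_symbol")
  cols <- intersect(cols, names(reports))
  reports <- unique(reports[cols])
  if (!nrow(reports)) {
    out <- data.frame(symbol = character(0), traits = character(0),
                      tissues = character(0), rvas = logical(0),
                      n_reports = integer(0), stringsAsFactors = FALSE)
    for (cl in .af_analysis_classes) out[[paste0("n_", tolower(cl))]] <- integer(0)
    return(out)
  }
  by_gene <- split(reports, reports$reported_symbol)
  rows <- lapply(names(by_gene), function(sym) {
    g <- by_gene[[sym]]
    traits <- setdiff(unique(g$trait[g$analysis_class %in%
                                       .af_association_classes]), "NONE")
    tissues <- setdiff(unique(g$tissue[g$analysis_class %in%
                                         .af_expression_classes]), "NONE")
    row <- data.frame(symbol = sym, traits = join_set(traits),
                      tissues = join_set(tissues),
                      rvas = any(g$analysis_class == "RVAS"),
                      n_reports = nrow(g), stringsAsFactors = FALSE)
    for (cl in .af_analysis_classes) {
      row[[paste0("n_", tolower(cl))]] <- sum(g$analysis_class == cl)
    }
    row
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$symbol), , drop = FALSE]
  rownames(out) <- NULL
  out
}
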