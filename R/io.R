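# Table readers/writers for the OpenTargets-style TSV exports the pipeline
# consumes. All tables are tab-separated UTF-8 with a mandatory header row;
# missing text values are empty strings, missing pocket scores use the
# sentinel ".". Set-valued columns (synonyms, tissues) are ";"-joined.

.af_missing_pocket <- "."

# column definitions per schema; type one of chr/num/int/lgl/set
.af_schemas <- list(
  gene_report = list(
    cols = c(study_id = "chr", analysis_class = "enum", trait = "enum",
             tissue = "enum", variant_id = "chr", reported_symbol = "chr",
             annotation_source = "enum"),
    enums = list(analysis_class = .af_analysis_classes, trait = .af_traits,
                 tissue = .af_tissues,
                 annotation_source = .af_annotation_sources)
  ),
  target_registry = list(
    cols = c(ensembl_id = "chr", hgnc_symbol = "chr", approved_name = "chr",
             biotype = "chr", synonyms = "chr", subcellular_locations = "chr",
             target_class = "chr"),
    enums = list()
  ),
  tractability = list(
    cols = c(ensembl_id = "chr", druggable_family = "lgl",
             pocket_score = "num", accessible_uniprot = "lgl",
             accessible_go = "lgl", accessible_hpa = "lgl"),
    enums = list()
  ),
  drug = list(
    cols = c(drug_id = "chr", name = "chr", drug_type = "chr",
             max_phase = "int", approved = "lgl", black_box = "chr",
             withdrawn = "lgl", synonyms = "chr"),
    enums = list()
  ),
  mechanism = list(
    cols = c(drug_id = "chr", action_type = "chr",
             target_ensembl_id = "chr", target_name = "chr",
             target_molecule_type = "chr"),
    enums = list()
  ),
  indication = list(
    cols = c(drug_id = "chr", ontology_term = "chr", decoded_label = "chr",
             specialty = "chr", secondary = "chr", evidence_source = "enum"),
    enums = list(evidence_source = .af_indication_sources)
  ),
  evidence_item = list(
    cols = c(drug_name = "chr", design_level = "enum", effect = "enum",
             comparator = "chr", population = "chr", estimate_text = "chr"),
    enums = list(
      design_level = setdiff(names(.af_level_rank), "NONE"),
      effect = setdiff(.af_effects, "NONE")
    )
  ),
  v2g = list(
    cols = c(variant_id = "chr", gene = "chr"),
    enums = list()
  ),
  manual_map = list(
    cols = c(reported_symbol = "chr", hgnc_symbol = "chr",
             ensembl_id = "chr"),
    enums = list()
  )
)

.af_parse_lgl <- function(x, field) {
  lx <- tolower(trimws(x))
  out <- rep(NA, length(x))
  out[lx %in% c("true", "t", "1", "yes", "y")] <- TRUE
  out[lx %in% c("false", "f", "0", "no", "n", "")] <- FALSE
  bad <- which(is.na(out))
  if (length(bad)) {
    stop(sprintf("validation error: field '%s' rows %s: not a boolean",
                 field, paste(bad, collapse = ", ")), call. = FALSE)
  }
  out
}

# row-level invariant checks; returns character vector of messages
.af_check_rows <- function(df, schema) {
  msgs <- character(0)
  if (schema == "gene_report") {
    has_tissue <- df$tissue != "NONE"
    is_expr <- df$analysis_class %in% .af_expression_classes
    bad <- which(has_tissue != is_expr)
    if (length(bad)) {
      msgs <- c(msgs, sprintf(
        "row %d: tissue must be set exactly for TWAS/EQTL_COLOC reports (class %s, tissue %s)",
        bad, df$analysis_class[bad], df$tissue[bad]))
    }
    assoc <- df$analysis_class %in% .af_association_classes
    bad <- which(assoc & df$trait == "NONE")
    if (length(bad)) {
      msgs <- c(msgs, sprintf(
        "row %d: trait must be set for association reports (class %s)",
        bad, df$analysis_class[bad]))
    }
  }
  if (schema == "tractability") {
    bad <- which(!is.na(df$pocket_score) &
                   (df$pocket_score < 0 | df$pocket_score > 1))
    if (length(bad)) {
      msgs <- c(msgs, sprintf("row %d: pocket_score %s outside [0,1]",
                              bad, df$pocket_score[bad]))
    }
  }
  if (schema == "drug") {
    bad <- which(is.na(df$max_phase) | df$max_phase < 0 | df$max_phase > 4)
    if (length(bad)) {
      msgs <- c(msgs, sprintf("row %d: max_phase must be an integer in 0..4",
                              bad))
    }
  }
  if (schema == "target_registry") {
    bad <- which(!nzchar(trimws(df$hgnc_symbol)))
    if (length(bad)) {
      msgs <- c(msgs, sprintf("row %d: hgnc_symbol must be non-empty", bad))
    }
    dup <- df$ensembl_id[duplicated(df$ensembl_id) & nzchar(df$ensembl_id)]
    if (length(dup)) {
      msgs <- c(msgs, sprintf("duplicated ensembl_id: %s",
                              paste(unique(dup), collapse = ", ")))
    }
  }
  msgs
}

#' Read a validated pipeline table
#'
#' Reads a tab-separated table with header and validates every row against
#' the named schema: enum columns are canonicalised to upper-case and checked
#' against their domain, typed columns are parsed, and type invariants (for
#' example that gene reports carry a tissue exactly when they come from a
#' TWAS or eQTL-colocalization analysis) are enforced with row numbers
#' reported for offending rows.
#'
#' @param path Path to a TSV file with a header row.
#' @param schema One of `"gene_report"`, `"target_registry"`,
#'   `"tractability"`, `"drug"`, `"mechanism"`, `"indication"`,
#'   `"evidence_item"`, `"v2g"`, `"manual_map"`.
#' @return A `data.frame`, one row per record, with a `"schema"` attribute.
#'   An empty file with only a header yields a zero-row frame.
#' @seealso [write_table()] for the inverse, [load_fixture()] for the
#'   packaged tables.
#' @export
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines("variant_id\tgene\nrs1\tSCN5A", f)
#' read_table(f, "v2g")
read_table <- function(path, schema) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sch <- .af_schemas[[schema]]
  if (is.null(sch)) {
    stop("unknown schema '", schema, "'; known: ",
         paste(names(.af_schemas), collapse = ", "), call. = FALSE)
  }
  df <- utils::read.delim(path, colClasses = "character",
                          check.names = FALSE, na.strings = NULL,
                          blank.lines.skip = TRUE, quote = "",
                          fileEncoding = "UTF-8")
  missing_cols <- setdiff(names(sch$cols), names(df))
  if (length(missing_cols)) {
    stop(sprintf("schema error: missing column(s) %s for schema '%s'",
                 paste(missing_cols, collapse = ", "), schema),
         call. = FALSE)
  }
  df <- df[names(sch$cols)]
  for (col in names(sch$cols)) {
    type <- sch$cols[[col]]
    if (type == "enum") {
      df[[col]] <- canonical_enum(df[[col]])
      dom <- sch$enums[[col]]
      bad <- which(!df[[col]] %in% dom)
      if (length(bad)) {
        stop(sprintf(
          "validation error: field '%s' row(s) %s: value(s) %s outside domain {%s}",
          col, paste(bad, collapse = ", "),
          paste(unique(df[[col]][bad]), collapse = ", "),
          paste(dom, collapse = ", ")), call. = FALSE)
      }
    } else if (type == "num") {
      raw <- trimws(df[[col]])
      miss <- raw %in% c(.af_missing_pocket, "")
      val <- suppressWarnings(as.numeric(raw))
      bad <- which(!miss & is.na(val))
      if (length(bad)) {
        stop(sprintf("validation error: field '%s' row(s) %s: not numeric",
                     col, paste(bad, collapse = ", ")), call. = FALSE)
      }
      val[miss] <- NA_real_
      df[[col]] <- val
    } else if (type == "int") {
      val <- suppressWarnings(as.integer(trimws(df[[col]])))
      df[[col]] <- val
    } else if (type == "lgl") {
      df[[col]] <- .af_parse_lgl(df[[col]], col)
    }
  }
  msgs <- .af_check_rows(df, schema)
  if (length(msgs)) {
    stop("validation error in '", basename(path), "':\n  ",
         paste(msgs, collapse = "\n  "), call. = FALSE)
  }
  attr(df, "schema") <- schema
  df
}

#' Write a pipeline table
#'
#' Writes records in the canonical column order for their schema as
#' tab-separated UTF-8 with a header row. Logical columns are written as
#' `TRUE`/`FALSE`, missing pocket scores as the `"."` sentinel and missing
#' text as the empty string, so that a read/write round trip of a canonical
#' file is byte-identical.
#'
#' @param records Data frame as returned by [read_table()].
#' @param path Output file path.
#' @param schema Schema name; defaults to the frame's `"schema"` attribute.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, schema = attr(records, "schema")) {
  if (is.null(schema)) stop("schema not given and not attached to records")
  sch <- .af_schemas[[schema]]
  if (is.null(sch)) stop("unknown schema '", schema, "'")
  missing_cols <- setdiff(names(sch$cols), names(records))
  if (length(missing_cols)) {
    stop("schema error: records lack column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  out <- records[names(sch$cols)]
  for (col in names(sch$cols)) {
    type <- sch$cols[[col]]
    if (type == "num") {
      out[[col]] <- vapply(out[[col]], function(x) {
        if (is.na(x)) .af_missing_pocket
        else format(x, trim = TRUE, scientific = FALSE)
      }, character(1))
    } else if (type == "lgl") {
      out[[col]] <- ifelse(out[[col]], "TRUE", "FALSE")
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "", fileEncoding = "UTF-8",
                     eol = "\n")
  invisible(path)
}
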