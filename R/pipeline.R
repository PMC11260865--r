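# End-to-end orchestration: harmonise -> score -> drug cross-reference ->
# evidence synthesis -> summaries, with a run log of stage counts and a
# checksummed manifest of the written artefacts.

#' Read a pipeline run configuration from YAML
#'
#' The file may set `input_dir`, `output_dir`, `gene_threshold`,
#' `druggability_threshold`, `condition` and `seed`; missing keys take the
#' defaults of [run_pipeline()].
#'
#' @param path Path to a YAML file.
#' @return A named list of configuration values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  known <- c("input_dir", "output_dir", "gene_threshold",
             "druggability_threshold", "condition", "seed")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg
}

#' Run the full prioritisation pipeline
#'
#' Executes every stage over an input world (an in-memory bundle from
#' [generate_world()], or a bundle directory written by [write_bundle()]):
#' variant-to-gene annotation with author fallback, symbol resolution with
#' synonym/manual fallback (unresolved symbols are logged, not guessed),
#' collapse to per-gene profiles, druggability and prioritisation scoring,
#' drug joining, salt-form deduplication, indication decoding, search-query
#' construction, evidence synthesis, and the three summary structures.
#' When `output_dir` is given, every artefact is written (TSV/JSON) and a
#' manifest of files with MD5 checksums plus a machine-readable run log of
#' stage counts are stored alongside.
#'
#' @param input A `"synthetic_world"`-shaped list of input frames, or a
#'   bundle directory path, or a YAML config path / list from
#'   [read_run_config()] whose `input_dir` points at a bundle.
#' @param output_dir Optional output directory.
#' @param gene_threshold,druggability_threshold Priority cut-offs
#'   (default 1; scores strictly greater flag priority).
#' @param condition Condition string for the literature queries.
#' @return An `"aftargets_run"` list with the stage outputs (`profiles`,
#'   `scores`, `links`, `parents`, `indications`, `queries`, `summary`,
#'   `adjacency`, `action_tree`, `trait_partition`), the `log` of stage
#'   counts, and (when written) the `manifest`.
#' @export
run_pipeline <- function(input, output_dir = NULL, gene_threshold = 1,
                         druggability_threshold = 1,
                         condition = "atrial fibrillation") {
  if (is.character(input) && length(input) == 1L) {
    if (dir.exists(input)) {
      input <- read_bundle(input)
    } else {
      input <- read_run_config(input)
    }
  }
  if (!is.null(input$input_dir) && is.null(input$gene_reports)) {
    cfg <- input
    input <- read_bundle(cfg$input_dir)
    if (is.null(output_dir)) output_dir <- cfg$output_dir
    if (!is.null(cfg$gene_threshold)) gene_threshold <- cfg$gene_threshold
    if (!is.null(cfg$druggability_threshold)) {
      druggability_threshold <- cfg$druggability_threshold
    }
    if (!is.null(cfg$condition)) condition <- cfg$condition
  }
  world <- input
  log <- list(n_reports_in = nrow(world$gene_reports))

  # 1. variant-to-gene annotation with author fallback
  reports <- annotate_variants(world$gene_reports, world$v2g)
  log$n_v2g_annotated <- sum(reports$annotation_source == "V2G" &
                               nzchar(reports$variant_id))
  log$n_author_annotated <- log$n_reports_in - log$n_v2g_annotated

  # 2. symbol resolution
  res <- resolve_symbols(unique(reports$reported_symbol), world$registry,
                         world$manual_map)
  idx <- match(reports$reported_symbol, res$reported_symbol)
  resolved <- res$resolved_symbol[idx]
  keep <- nzchar(resolved)
  log$n_reports_unresolved <- sum(!keep)
  log$unresolved_symbols <- attr(res, "unresolved")
  reports$reported_symbol[keep] <- resolved[keep]
  reports <- reports[keep, , drop = FALSE]

  # 3. collapse to per-gene profiles
  profiles <- collapse_reports(reports)
  profiles$ensembl_id <- world$registry$ensembl_id[
    match(profiles$symbol, world$registry$hgnc_symbol)]
  log$n_genes_resolved <- nrow(profiles)

  # 4. scoring
  scores <- score_targets(profiles, world$tractability,
                          gene_threshold = gene_threshold,
                          druggability_threshold = druggability_threshold)
  scores <- rank_targets(scores)
  log$n_targets_prioritised <- sum(scores$gene_priority)

  # 5. drug joining
  targets <- world$registry[world$registry$hgnc_symbol %in%
                              profiles$symbol, , drop = FALSE]
  links <- join_targets_to_drugs(targets, world$mechanisms, world$drugs)
  log$n_links <- nrow(links)
  log$n_drugged_targets <- length(unique(links$ensembl_id))

  # 6. deduplication
  parents <- deduplicate_drugs(
    world$drugs,
    salt_lexicon = world$salt_lexicon %||% load_fixture("SALT_LEXICON"),
    conjugate_whitelist = world$conjugate_whitelist %||%
      load_fixture("CONJUGATE_WHITELIST"))
  log$n_drug_forms <- nrow(world$drugs)
  log$n_parent_drugs <- nrow(parents)

  # 7. indication decoding
  indications <- decode_indications(world$indications, world$ontology_map)
  log$n_indications <- nrow(indications)
  log$n_unmapped_terms <- length(attr(indications, "unmapped"))

  # 8. literature queries
  queries <- build_search_queries(parents$parent_drug_key,
                                  condition = condition)
  log$n_queries <- nrow(queries)

  # 9. evidence synthesis
  summary <- assemble_summary(parents, links, scores,
                              world$evidence_items,
                              world$guideline_list %||% character(0),
                              drugs = world$drugs)
  log$n_drugs_with_evidence <- nrow(summary)

  # 10. summary structures
  adjacency <- indication_adjacency(indications,
                                    attr(parents, "membership"))
  tree <- action_dendrogram(links, scores)
  partition <- partition_by_trait(profiles, links)

  run <- list(profiles = profiles, scores = scores, links = links,
              parents = parents, indications = indications,
              queries = queries, summary = summary, adjacency = adjacency,
              action_tree = tree, trait_partition = partition, log = log)
  class(run) <- "aftargets_run"

  if (!is.null(output_dir)) {
    run$manifest <- .af_write_run(run, output_dir)
  }
  run
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.af_write_df <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "", fileEncoding = "UTF-8")
  path
}

.af_write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    .af_write_df(run$profiles, file.path(dir, "profiles.tsv")),
    .af_write_df(run$scores, file.path(dir, "scores.tsv")),
    .af_write_df(run$links, file.path(dir, "links.tsv")),
    .af_write_df(run$parents, file.path(dir, "parent_drugs.tsv")),
    .af_write_df(run$indications, file.path(dir, "indications.tsv")),
    .af_write_df(run$queries, file.path(dir, "queries.tsv")),
    .af_write_df(run$summary, file.path(dir, "evidence_summary.tsv"))
  )
  adj <- file.path(dir, "indication_adjacency.tsv")
  m <- run$adjacency$matrix
  utils::write.table(cbind(category = rownames(m), as.data.frame(m)), adj,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, adj)
  tree_path <- file.path(dir, "action_tree.json")
  writeLines(tree_to_json(run$action_tree), tree_path)
  newick_path <- file.path(dir, "action_tree.newick")
  writeLines(tree_to_newick(run$action_tree), newick_path)
  part_path <- file.path(dir, "trait_partition.json")
  jsonlite::write_json(as.list(run$trait_partition), part_path,
                       auto_unbox = TRUE, digits = NA)
  log_path <- file.path(dir, "run_log.json")
  jsonlite::write_json(run$log, log_path, auto_unbox = TRUE, digits = NA)
  files <- c(files, tree_path, newick_path, part_path, log_path)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}

#' @export
print.aftargets_run <- function(x, ...) {
  l <- x$log
  cat("Prioritisation pipeline run\n")
  cat(sprintf("  reports in:          %d (%d V2G, %d author-annotated)\n",
              l$n_reports_in, l$n_v2g_annotated, l$n_author_annotated))
  cat(sprintf("  genes resolved:      %d (%d report(s) unresolved)\n",
              l$n_genes_resolved, l$n_reports_unresolved))
  cat(sprintf("  priority targets:    %d\n", l$n_targets_prioritised))
  cat(sprintf("  drugged targets:     %d via %d links\n",
              l$n_drugged_targets, l$n_links))
  cat(sprintf("  parent drugs:        %d (from %d forms)\n",
              l$n_parent_drugs, l$n_drug_forms))
  cat(sprintf("  drugs with evidence: %d\n", l$n_drugs_with_evidence))
  invisible(x)
}
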