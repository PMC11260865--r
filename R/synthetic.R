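# Seeded synthetic-data generators. A generated "world" contains every input
# table the pipeline consumes, with a ground-truth ledger recording the
# planted priority-gene set, the true parent-drug partition, and the true
# trait/tissue assignments, so that end-to-end parameter recovery can be
# checked exactly. Names use a pronounceable-token scheme disjoint from real
# gene and drug nomenclature.

.af_target_classes <- c("Ion channel", "Enzyme", "Membrane receptor",
                        "Transcription factor", "Transporter",
                        "Unclassified protein")
.af_action_types <- c("INHIBITOR", "AGONIST", "ANTAGONIST", "BLOCKER",
                      "ACTIVATOR", "MODULATOR")
.af_specialties <- c("CARDIOLOGY", "ONCOLOGY", "NEUROLOGY", "RESPIRATORY",
                     "ENDOCRINOLOGY", "PSYCHIATRY", "RHEUMATOLOGY",
                     "INFECTIOUS_DISEASE")

# sample k elements of x (safe for length-1 x, unlike sample())
.af_sample <- function(x, k, ...) x[sample.int(length(x), k, ...)]

# pronounceable token: alternating consonant/vowel syllables + unique index
.af_make_names <- function(n, n_syllables = 3, prefix = "") {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t",
            "v", "z")
  vow <- c("a", "e", "i", "o", "u")
  vapply(seq_len(n), function(i) {
    syl <- paste0(sample(cons, n_syllables, replace = TRUE),
                  sample(vow, n_syllables, replace = TRUE))
    paste0(prefix, paste(syl, collapse = ""), i)
  }, character(1))
}

#' Configuration for the synthetic-world generator
#'
#' Collects and validates the knobs of [generate_world()]. Defaults describe
#' a small but structurally faithful world: sparse multi-study gene evidence
#' with a planted subset of priority genes, tiered tractability, salt-form
#' drug duplicates with a few active-moiety conjugates, many-to-many
#' drug-target links, ontology-coded indications with a DailyMed-sourced
#' minority, and per-drug evidence items with at most one guideline drug
#' flagging per drug.
#'
#' @param seed Integer RNG seed.
#' @param n_genes Number of genes in the registry.
#' @param n_studies Number of studies reports are spread over.
#' @param planted_priority_fraction Fraction of genes planted with a
#'   prioritisation score above 1 (the rest score at most 1).
#' @param nonpriority_pattern_probs Probabilities that a non-planted gene
#'   has no evidence, a single trait, or a single tissue.
#' @param rvas_prob Probability that a planted gene's extra evidence comes
#'   from a rare-variant analysis.
#' @param v2g_coverage Fraction of report variants present in the
#'   variant-to-gene table (the remainder fall back to author annotation).
#' @param synonym_prob Probability a registry gene carries a synonym.
#' @param n_parent_drugs Number of parent drugs.
#' @param salt_form_probs Distribution of formulations per parent (names are
#'   the multiplicities).
#' @param conjugate_fraction Fraction of parents that are two-moiety
#'   conjugates (kept distinct at dedup via the generated whitelist).
#' @param drugged_gene_fraction Fraction of genes eligible as drug targets.
#' @param targets_per_drug Candidate numbers of targets per parent drug.
#' @param indications_per_drug Candidate numbers of indications per parent.
#' @param dailymed_prob Probability an indication row is DailyMed-sourced.
#' @param evidence_prob Probability a parent drug has evidence items.
#' @param evidence_level_probs Named sampling distribution over design
#'   levels for evidence items.
#' @param effect_probs Named sampling distribution over item effects.
#' @param guideline_prob Probability a drug with evidence is on an AF
#'   guideline.
#' @param tractability_family_prob,tractability_pocket_missing_prob,
#'   tractability_accessible_prob Tractability tier probabilities.
#' @return A validated `"generator_config"` list.
#' @export
generator_config <- function(seed = 1L,
                             n_genes = 200L,
                             n_studies = 40L,
                             planted_priority_fraction = 0.2,
                             nonpriority_pattern_probs =
                               c(none = 0.2, trait = 0.6, tissue = 0.2),
                             rvas_prob = 0.3,
                             v2g_coverage = 0.7,
                             synonym_prob = 0.4,
                             n_parent_drugs = 60L,
                             salt_form_probs = c("1" = 0.6, "2" = 0.3,
                                                 "3" = 0.1),
                             conjugate_fraction = 0.05,
                             drugged_gene_fraction = 0.4,
                             targets_per_drug = 1:3,
                             indications_per_drug = 1:3,
                             dailymed_prob = 0.15,
                             evidence_prob = 0.5,
                             evidence_level_probs =
                               c(SYSTEMATIC_REVIEW = 0.15, RCT = 0.35,
                                 OBSERVATIONAL = 0.5),
                             effect_probs = c(BENEFICIAL = 0.35,
                                              HARMFUL = 0.2, NEUTRAL = 0.35,
                                              POTENTIAL_HARM = 0.1),
                             guideline_prob = 0.1,
                             tractability_family_prob = 0.4,
                             tractability_pocket_missing_prob = 0.4,
                             tractability_accessible_prob = 0.3) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_studies = as.integer(n_studies),
              planted_priority_fraction = planted_priority_fraction,
              nonpriority_pattern_probs = nonpriority_pattern_probs,
              rvas_prob = rvas_prob, v2g_coverage = v2g_coverage,
              synonym_prob = synonym_prob,
              n_parent_drugs = as.integer(n_parent_drugs),
              salt_form_probs = salt_form_probs,
              conjugate_fraction = conjugate_fraction,
              drugged_gene_fraction = drugged_gene_fraction,
              targets_per_drug = targets_per_drug,
              indications_per_drug = indications_per_drug,
              dailymed_prob = dailymed_prob, evidence_prob = evidence_prob,
              evidence_level_probs = evidence_level_probs,
              effect_probs = effect_probs, guideline_prob = guideline_prob,
              tractability_family_prob = tractability_family_prob,
              tractability_pocket_missing_prob =
                tractability_pocket_missing_prob,
              tractability_accessible_prob = tractability_accessible_prob)
  probs <- c(cfg$planted_priority_fraction, cfg$nonpriority_pattern_probs,
             cfg$rvas_prob, cfg$v2g_coverage, cfg$synonym_prob,
             cfg$salt_form_probs, cfg$conjugate_fraction,
             cfg$drugged_gene_fraction, cfg$dailymed_prob,
             cfg$evidence_prob, cfg$evidence_level_probs, cfg$effect_probs,
             cfg$guideline_prob, cfg$tractability_family_prob,
             cfg$tractability_pocket_missing_prob,
             cfg$tractability_accessible_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("config error: all probabilities must lie in [0,1]", call. = FALSE)
  }
  if (cfg$n_genes < 1L || cfg$n_studies < 1L || cfg$n_parent_drugs < 1L) {
    stop("config error: counts must be positive", call. = FALSE)
  }
  if (round(cfg$planted_priority_fraction * cfg$n_genes) > cfg$n_genes) {
    stop("config error: more planted priority genes than genes",
         call. = FALSE)
  }
  class(cfg) <- "generator_config"
  cfg
}

# run expr with the RNG seeded from cfg, restoring the caller's RNG state
.af_with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a full synthetic input world with ground truth
#'
#' Emits every table the pipeline consumes — target registry, tractability,
#' variant-to-gene lookup, per-study gene reports, drugs (with planted
#' salt-form duplicates and conjugates), mechanisms, indications (with an
#' ontology map and a DailyMed minority), evidence items and a guideline
#' list — together with a `truth` ledger recording the planted priority-gene
#' set, the parent-drug partition, the per-gene trait/tissue/rare-variant
#' assignments and the variant-to-gene coverage split. Generation is fully
#' deterministic under the config seed; the caller's RNG state is left
#' untouched.
#'
#' @param config A [generator_config()].
#' @return A `"synthetic_world"` list of input frames plus `truth`.
#' @export
#' @examples
#' w <- generate_world(generator_config(seed = 7, n_genes = 30,
#'                                      n_parent_drugs = 10))
#' length(w$truth$priority_genes)
generate_world <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  .af_with_seed(config$seed, {
    n <- config$n_genes
    symbols <- toupper(.af_make_names(n, n_syllables = 2, prefix = "zz"))
    ensembl <- sprintf("SYNG%05d", seq_len(n))
    has_syn <- stats::runif(n) < config$synonym_prob
    synonyms <- ifelse(has_syn, paste0("ALT", symbols), "")
    registry <- data.frame(
      ensembl_id = ensembl, hgnc_symbol = symbols,
      approved_name = paste("synthetic protein", seq_len(n)),
      biotype = "protein_coding", synonyms = synonyms,
      subcellular_locations = sample(c("Cell membrane", "Cytoplasm",
                                       "Nucleus", "Secreted"), n, TRUE),
      target_class = sample(.af_target_classes, n, TRUE),
      stringsAsFactors = FALSE
    )
    attr(registry, "schema") <- "target_registry"

    pocket <- round(stats::runif(n), 2)
    pocket[stats::runif(n) < config$tractability_pocket_missing_prob] <-
      NA_real_
    tractability <- data.frame(
      ensembl_id = ensembl,
      druggable_family = stats::runif(n) < config$tractability_family_prob,
      pocket_score = pocket,
      accessible_uniprot = stats::runif(n) <
        config$tractability_accessible_prob,
      accessible_go = stats::runif(n) <
        config$tractability_accessible_prob,
      accessible_hpa = stats::runif(n) <
        config$tractability_accessible_prob,
      stringsAsFactors = FALSE
    )
    attr(tractability, "schema") <- "tractability"

    # --- plant per-gene evidence patterns -------------------------------
    n_priority <- round(config$planted_priority_fraction * n)
    priority_idx <- if (n_priority) sample(n, n_priority) else integer(0)
    traits <- vector("list", n)
    tissues <- vector("list", n)
    rvas <- logical(n)
    for (i in seq_len(n)) {
      if (i %in% priority_idx) {
        # score >= 2: one trait plus rare-variant support, or >= 2 further
        # trait/tissue domains
        traits[[i]] <- sample(.af_score_traits, sample(1:2, 1))
        if (stats::runif(1) < config$rvas_prob) {
          rvas[i] <- TRUE
        } else if (length(traits[[i]]) < 2) {
          tissues[[i]] <- sample(.af_score_tissues, sample(1:2, 1))
        } else if (stats::runif(1) < 0.5) {
          tissues[[i]] <- sample(.af_score_tissues, 1)
        }
      } else {
        pat <- sample(names(config$nonpriority_pattern_probs), 1,
                      prob = config$nonpriority_pattern_probs)
        if (pat == "trait") traits[[i]] <- sample(.af_score_traits, 1)
        if (pat == "tissue") tissues[[i]] <- sample(.af_score_tissues, 1)
      }
    }
    score <- lengths(traits) + lengths(tissues) + as.integer(rvas)

    # --- reports --------------------------------------------------------
    studies <- sprintf("STUDY%03d", seq_len(config$n_studies))
    report_rows <- list()
    variant_counter <- 0L
    for (i in seq_len(n)) {
      for (tr in traits[[i]]) {
        variant_counter <- variant_counter + 1L
        cl <- if (rvas[i] && tr == traits[[i]][1]) "RVAS" else
          sample(c("GWAS_SNP", "WGS", "EXWAS", "REPLICATION"), 1,
                 prob = c(0.6, 0.1, 0.2, 0.1))
        report_rows[[length(report_rows) + 1L]] <- data.frame(
          study_id = sample(studies, 1), analysis_class = cl, trait = tr,
          tissue = "NONE", variant_id = sprintf("sv%05d", variant_counter),
          reported_symbol = symbols[i], annotation_source = "AUTHOR",
          stringsAsFactors = FALSE)
      }
      for (ts in tissues[[i]]) {
        report_rows[[length(report_rows) + 1L]] <- data.frame(
          study_id = sample(studies, 1),
          analysis_class = sample(c("TWAS", "EQTL_COLOC"), 1),
          trait = "NONE", tissue = ts, variant_id = "",
          reported_symbol = symbols[i], annotation_source = "AUTHOR",
          stringsAsFactors = FALSE)
      }
    }
    gene_reports <- if (length(report_rows)) do.call(rbind, report_rows)
    else data.frame(study_id = character(0), analysis_class = character(0),
                    trait = character(0), tissue = character(0),
                    variant_id = character(0),
                    reported_symbol = character(0),
                    annotation_source = character(0),
                    stringsAsFactors = FALSE)
    attr(gene_reports, "schema") <- "gene_report"

    # --- variant-to-gene table ------------------------------------------
    variants <- gene_reports$variant_id[nzchar(gene_reports$variant_id)]
    v2g_genes <- gene_reports$reported_symbol[
      nzchar(gene_reports$variant_id)]
    covered <- stats::runif(length(variants)) < config$v2g_coverage
    v2g <- data.frame(variant_id = variants[covered],
                      gene = v2g_genes[covered], stringsAsFactors = FALSE)
    attr(v2g, "schema") <- "v2g"

    # --- drugs: parents, salt forms, conjugates -------------------------
    np <- config$n_parent_drugs
    parent_names <- .af_make_names(np, n_syllables = 3)
    n_conj <- round(config$conjugate_fraction * np)
    conj_idx <- if (n_conj) sample(np, n_conj) else integer(0)
    conj_suffix <- .af_make_names(max(n_conj, 1L), n_syllables = 2)
    parent_names[conj_idx] <-
      paste(parent_names[conj_idx], conj_suffix[seq_along(conj_idx)])
    salt_tokens <- c("hydrochloride", "tartrate", "succinate", "sodium",
                     "mesylate", "fumarate", "maleate", "citrate")
    mult <- sample(as.integer(names(config$salt_form_probs)), np,
                   replace = TRUE, prob = config$salt_form_probs)
    mult[conj_idx] <- 1L  # conjugates are single-form
    drug_rows <- list()
    membership_rows <- list()
    form_counter <- 0L
    for (p in seq_len(np)) {
      forms <- parent_names[p]
      if (mult[p] > 1L) {
        forms <- c(forms, paste(parent_names[p],
                                sample(salt_tokens, mult[p] - 1L)))
      }
      for (f in forms) {
        form_counter <- form_counter + 1L
        id <- sprintf("SDRG%04d", form_counter)
        drug_rows[[form_counter]] <- data.frame(
          drug_id = id, name = f,
          drug_type = sample(c("Small molecule", "Antibody", "Protein"), 1,
                             prob = c(0.8, 0.1, 0.1)),
          max_phase = sample(0:4, 1), approved = stats::runif(1) < 0.5,
          black_box = "", withdrawn = stats::runif(1) < 0.05,
          synonyms = "", stringsAsFactors = FALSE)
        membership_rows[[form_counter]] <- data.frame(
          drug_id = id, name = f, parent_drug_key = parent_names[p],
          stringsAsFactors = FALSE)
      }
    }
    drugs <- do.call(rbind, drug_rows)
    attr(drugs, "schema") <- "drug"
    parent_partition <- do.call(rbind, membership_rows)

    # --- mechanisms ------------------------------------------------------
    n_drugged <- max(1L, round(config$drugged_gene_fraction * n))
    drugged_pool <- sample(n, n_drugged)
    mech_rows <- list()
    parent_targets <- vector("list", np)
    for (p in seq_len(np)) {
      k <- sample(config$targets_per_drug, 1)
      parent_targets[[p]] <- .af_sample(drugged_pool, min(k, n_drugged))
      action <- sample(.af_action_types, length(parent_targets[[p]]),
                       replace = TRUE)
      ids <- parent_partition$drug_id[
        parent_partition$parent_drug_key == parent_names[p]]
      for (id in ids) {
        mech_rows[[length(mech_rows) + 1L]] <- data.frame(
          drug_id = id, action_type = action,
          target_ensembl_id = ensembl[parent_targets[[p]]],
          target_name = symbols[parent_targets[[p]]],
          target_molecule_type = "Protein", stringsAsFactors = FALSE)
      }
    }
    mechanisms <- do.call(rbind, mech_rows)
    attr(mechanisms, "schema") <- "mechanism"

    # --- indications + ontology map -------------------------------------
    terms <- sprintf("OT:%04d", seq_along(.af_specialties))
    ontology_map <- data.frame(
      ontology_term = terms, specialty = .af_specialties,
      secondary = "", decoded_label = tolower(.af_specialties),
      stringsAsFactors = FALSE)
    ind_rows <- list()
    for (p in seq_len(np)) {
      k <- sample(config$indications_per_drug, 1)
      cats <- sample(seq_along(terms), min(k, length(terms)))
      id <- parent_partition$drug_id[
        parent_partition$parent_drug_key == parent_names[p]][1]
      for (ci in cats) {
        src <- if (stats::runif(1) < config$dailymed_prob) "DAILYMED" else
          sample(c("TRIAL", "ATC", "FDA_LABEL"), 1)
        ind_rows[[length(ind_rows) + 1L]] <- data.frame(
          drug_id = id, ontology_term = terms[ci],
          decoded_label = tolower(.af_specialties[ci]), specialty = "",
          secondary = "", evidence_source = src, stringsAsFactors = FALSE)
      }
    }
    indications <- do.call(rbind, ind_rows)
    attr(indications, "schema") <- "indication"

    # --- evidence items + guideline list --------------------------------
    ev_rows <- list()
    guideline_list <- character(0)
    for (p in seq_len(np)) {
      if (stats::runif(1) >= config$evidence_prob) next
      in_guideline <- stats::runif(1) < config$guideline_prob
      if (in_guideline) guideline_list <- c(guideline_list,
                                            parent_names[p])
      k <- sample(1:3, 1)
      for (j in seq_len(k)) {
        lvl <- sample(names(config$evidence_level_probs), 1,
                      prob = config$evidence_level_probs)
        ev_rows[[length(ev_rows) + 1L]] <- data.frame(
          drug_name = parent_names[p], design_level = lvl,
          effect = sample(names(config$effect_probs), 1,
                          prob = config$effect_probs),
          comparator = "", population = "synthetic cohort",
          estimate_text = "", stringsAsFactors = FALSE)
      }
    }
    evidence_items <- if (length(ev_rows)) do.call(rbind, ev_rows) else
      data.frame(drug_name = character(0), design_level = character(0),
                 effect = character(0), comparator = character(0),
                 population = character(0), estimate_text = character(0),
                 stringsAsFactors = FALSE)
    attr(evidence_items, "schema") <- "evidence_item"

    truth <- list(
      priority_genes = sort(symbols[priority_idx]),
      gene_patterns = data.frame(
        symbol = symbols,
        traits = vapply(traits, join_set, character(1)),
        tissues = vapply(tissues, join_set, character(1)),
        rvas = rvas, score = score, stringsAsFactors = FALSE),
      parent_partition = parent_partition,
      parent_names = sort(unique(parent_names)),
      conjugate_parents = sort(parent_names[conj_idx]),
      v2g_variants = sort(variants[covered]),
      author_variants = sort(variants[!covered]),
      drugged_genes = sort(symbols[drugged_pool]),
      guideline_list = sort(unique(guideline_list)),
      n_dailymed = sum(indications$evidence_source == "DAILYMED")
    )

    world <- list(config = config, registry = registry,
                  tractability = tractability, v2g = v2g,
                  gene_reports = gene_reports, drugs = drugs,
                  mechanisms = mechanisms, indications = indications,
                  ontology_map = ontology_map,
                  evidence_items = evidence_items,
                  guideline_list = truth$guideline_list,
                  conjugate_whitelist = truth$conjugate_parents,
                  salt_lexicon = salt_tokens, truth = truth)
    class(world) <- "synthetic_world"
    world
  })
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(paste0(
    "Synthetic world (seed %d): %d genes (%d planted priority), ",
    "%d reports, %d drug forms over %d parents, %d evidence items\n"),
    x$config$seed, nrow(x$registry), length(x$truth$priority_genes),
    nrow(x$gene_reports), nrow(x$drugs),
    length(unique(x$truth$parent_partition$parent_drug_key)),
    nrow(x$evidence_items)))
  invisible(x)
}

#' Apply a targeted perturbation to a synthetic world
#'
#' Negative-path perturbations for testing the pipeline's failure handling:
#' \describe{
#'   \item{drop_v2g}{removes a fraction of variant-to-gene rows (the first
#'     rows in variant order), so the author-annotated fraction rises by
#'     exactly the number of dropped variants.}
#'   \item{scramble_symbols}{replaces reported symbols with their registry
#'     synonyms wherever one exists, forcing synonym-stage resolution.}
#'   \item{inject_dailymed}{appends DailyMed-sourced indication rows, which
#'     decoding must remove.}
#'   \item{dangling_mechanism}{appends a mechanism row referencing an
#'     unknown drug id, which the drug join must reject.}
#' }
#'
#' @param world A `"synthetic_world"` from [generate_world()].
#' @param mode One of the modes above.
#' @param fraction Fraction of v2g rows to drop (mode `drop_v2g`).
#' @param n Number of rows to inject (mode `inject_dailymed`).
#' @return The perturbed world; `drop_v2g` records the removed variants in
#'   the `dropped_variants` truth entry.
#' @export
corrupt <- function(world, mode, fraction = 0.5, n = 3L) {
  stopifnot(inherits(world, "synthetic_world"))
  if (mode == "drop_v2g") {
    ord <- order(world$v2g$variant_id)
    k <- ceiling(fraction * nrow(world$v2g))
    drop <- ord[seq_len(k)]
    world$truth$dropped_variants <- sort(world$v2g$variant_id[drop])
    world$truth$v2g_variants <- setdiff(world$truth$v2g_variants,
                                        world$truth$dropped_variants)
    world$truth$author_variants <- sort(c(world$truth$author_variants,
                                          world$truth$dropped_variants))
    world$v2g <- world$v2g[-drop, , drop = FALSE]
    rownames(world$v2g) <- NULL
  } else if (mode == "scramble_symbols") {
    idx <- match(world$gene_reports$reported_symbol,
                 world$registry$hgnc_symbol)
    syn <- world$registry$synonyms[idx]
    has <- !is.na(idx) & nzchar(syn)
    world$gene_reports$reported_symbol[has] <- syn[has]
  } else if (mode == "inject_dailymed") {
    extra <- world$indications[rep(1L, n), , drop = FALSE]
    extra$evidence_source <- "DAILYMED"
    world$indications <- rbind(world$indications, extra)
    rownames(world$indications) <- NULL
  } else if (mode == "dangling_mechanism") {
    bad <- world$mechanisms[1L, , drop = FALSE]
    bad$drug_id <- "SDRG_MISSING"
    world$mechanisms <- rbind(world$mechanisms, bad)
    rownames(world$mechanisms) <- NULL
  } else {
    stop("unknown corrupt mode: ", mode, call. = FALSE)
  }
  world
}

#' Write a synthetic world to a bundle directory
#'
#' Serialises every input table as TSV (via [write_table()]), the word lists
#' as plain text and the ground-truth ledger as JSON.
#'
#' @param world A `"synthetic_world"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @seealso [read_bundle()] for the inverse.
#' @export
write_bundle <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table(world$registry, file.path(dir, "registry.tsv"))
  write_table(world$tractability, file.path(dir, "tractability.tsv"))
  write_table(world$v2g, file.path(dir, "v2g.tsv"))
  write_table(world$gene_reports, file.path(dir, "gene_reports.tsv"))
  write_table(world$drugs, file.path(dir, "drugs.tsv"))
  write_table(world$mechanisms, file.path(dir, "mechanisms.tsv"))
  write_table(world$indications, file.path(dir, "indications.tsv"))
  write_table(world$evidence_items, file.path(dir, "evidence_items.tsv"))
  utils::write.table(world$ontology_map, file.path(dir, "ontology_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(world$guideline_list, file.path(dir, "guideline_list.txt"))
  writeLines(world$conjugate_whitelist,
             file.path(dir, "conjugate_whitelist.txt"))
  writeLines(world$salt_lexicon, file.path(dir, "salt_lexicon.txt"))
  jsonlite::write_json(world$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a bundle directory back into a world
#'
#' @param dir A directory written by [write_bundle()].
#' @return A `"synthetic_world"`-shaped list (without `config`).
#' @export
read_bundle <- function(dir) {
  world <- list(
    registry = read_table(file.path(dir, "registry.tsv"),
                          "target_registry"),
    tractability = read_table(file.path(dir, "tractability.tsv"),
                              "tractability"),
    v2g = read_table(file.path(dir, "v2g.tsv"), "v2g"),
    gene_reports = read_table(file.path(dir, "gene_reports.tsv"),
                              "gene_report"),
    drugs = read_table(file.path(dir, "drugs.tsv"), "drug"),
    mechanisms = read_table(file.path(dir, "mechanisms.tsv"), "mechanism"),
    indications = read_table(file.path(dir, "indications.tsv"),
                             "indication"),
    ontology_map = utils::read.delim(file.path(dir, "ontology_map.tsv"),
                                     colClasses = "character"),
    evidence_items = read_table(file.path(dir, "evidence_items.tsv"),
                                "evidence_item"),
    guideline_list = readLines(file.path(dir, "guideline_list.txt")),
    conjugate_whitelist = readLines(file.path(dir,
                                              "conjugate_whitelist.txt")),
    salt_lexicon = readLines(file.path(dir, "salt_lexicon.txt")),
    truth = jsonlite::read_json(file.path(dir, "truth.json"),
                                simplifyVector = TRUE)
  )
  class(world) <- "synthetic_world"
  world
}
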