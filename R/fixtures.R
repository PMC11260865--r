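# Packaged fixtures: transcriptions of the published drugged-target table
# (Table 1 style: 68 targets with approved name, subcellular location, target
# class and per-tissue TWAS/eQTL evidence) and the drug clinical-evidence
# table (Table 2 style: per-drug maximum evidence level, overall effect,
# warnings, withdrawal and a bold/priority flag), plus the printed gene lists
# and the dedup lexicons. Each file is checksummed against a manifest.

.af_fixture_files <- c(
  TABLE1 = "table1_targets.tsv",
  TABLE2 = "table2_evidence.tsv",
  BP_TARGETS = "bp_associated_targets.txt",
  UNDRUGGABLE_TARGETS = "undruggable_drugged_targets.txt",
  SALT_LEXICON = "salt_lexicon.txt",
  CONJUGATE_WHITELIST = "conjugate_whitelist.txt"
)

.af_extdata <- function(file = "") {
  system.file("extdata", file, package = "aftargets", mustWork = FALSE)
}

.af_check_fixture <- function(file, dir = NULL) {
  manifest_path <- if (is.null(dir)) .af_extdata("fixture_manifest.tsv")
    else file.path(dir, "fixture_manifest.tsv")
  path <- if (is.null(dir)) .af_extdata(file) else file.path(dir, file)
  if (!file.exists(path)) stop("packaged fixture missing: ", file)
  if (!file.exists(manifest_path)) stop("fixture manifest missing")
  manifest <- utils::read.delim(manifest_path, colClasses = "character")
  expected <- manifest$md5[manifest$file == file]
  if (length(expected) != 1L) {
    stop("fixture-corruption error: '", file, "' not listed in manifest")
  }
  observed <- unname(tools::md5sum(path))
  if (!identical(observed, expected)) {
    stop("fixture-corruption error: checksum mismatch for '", file,
         "' (expected ", expected, ", got ", observed, ")")
  }
  path
}

# read a comment-headed one-symbol-per-line list
.af_read_list <- function(path) {
  x <- readLines(path, encoding = "UTF-8")
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

# split "Neutral (Compared with other drug in same class)" into effect and
# comparator annotation
.af_split_effect <- function(x) {
  comparator <- rep("", length(x))
  has <- grepl("\\(", x)
  comparator[has] <- sub("^.*\\(([^)]*)\\).*$", "\\1", x[has])
  effect <- canonical_enum(trimws(sub("\\s*\\(.*$", "", x)))
  list(effect = effect, comparator = comparator)
}

# strip reported-alias parentheticals from a symbol list cell:
# "AOPEP (C9orf3), ENPEP" -> c("AOPEP", "ENPEP")
.af_parse_symbols <- function(x) {
  lapply(x, function(cell) {
    cell <- gsub("\\s*\\([^)]*\\)", "", cell)
    split_set(cell, sep = ",")
  })
}

#' Load a packaged fixture
#'
#' Loads one of the fixtures transcribed from the published tables, after
#' verifying its checksum against the packaged manifest. `"TABLE1"` is the
#' drugged-target table (one row per target, with TWAS and eQTL tissue sets
#' parsed into list columns); `"TABLE2"` is the drug clinical-evidence table
#' (maximum evidence level and overall effect canonicalised, comparator
#' annotations split out, and the bold high-priority flag as a logical).
#' `"BP_TARGETS"` and `"UNDRUGGABLE_TARGETS"` are the printed gene lists;
#' `"SALT_LEXICON"` and `"CONJUGATE_WHITELIST"` the dedup word lists.
#'
#' @param name One of `"TABLE1"`, `"TABLE2"`, `"BP_TARGETS"`,
#'   `"UNDRUGGABLE_TARGETS"`, `"SALT_LEXICON"`, `"CONJUGATE_WHITELIST"`.
#' @return A data frame for the two tables; a character vector for the lists.
#' @export
#' @examples
#' t1 <- load_fixture("TABLE1")
#' nrow(t1)                        # 68 drugged targets
#' t1$eqtl[t1$hgnc_symbol == "KCNJ5"]
load_fixture <- function(name = c("TABLE1", "TABLE2", "BP_TARGETS",
                                  "UNDRUGGABLE_TARGETS", "SALT_LEXICON",
                                  "CONJUGATE_WHITELIST")) {
  name <- match.arg(name)
  path <- .af_check_fixture(.af_fixture_files[[name]])
  if (name == "TABLE1") {
    df <- utils::read.delim(path, colClasses = "character", quote = "",
                            na.strings = NULL, fileEncoding = "UTF-8")
    df$twas <- lapply(df$twas_tissues, split_set, sep = ",")
    df$eqtl <- lapply(df$eqtl_tissues, split_set, sep = ",")
    return(df)
  }
  if (name == "TABLE2") {
    df <- utils::read.delim(path, colClasses = "character", quote = "",
                            na.strings = NULL, fileEncoding = "UTF-8")
    eff <- .af_split_effect(df$overall_effect)
    out <- data.frame(
      drug_name = df$drug_name,
      target_symbols = df$target_symbols,
      max_level = canonical_enum(df$max_level),
      overall_effect = eff$effect,
      comparator = eff$comparator,
      black_box = df$black_box,
      withdrawn = tolower(df$withdrawn) %in% c("yes", "true"),
      high_priority = toupper(df$high_priority) == "TRUE",
      stringsAsFactors = FALSE
    )
    out$targets <- .af_parse_symbols(df$target_symbols)
    return(out)
  }
  .af_read_list(path)
}

#' Check packaged fixtures against their invariants
#'
#' Re-derives the structural facts the packaged fixtures must satisfy: the
#' drugged-target table has exactly 68 rows with unique symbols and valid
#' tissue sets, the drug-evidence table's level and effect columns lie in
#' their domains with 21 Guideline and 15 Observational rows, the printed
#' blood-pressure list has 31 symbols and the not-druggable list 12, and all
#' checksums match the manifest.
#'
#' @return Invisibly, a data frame with one row per check (`check`,
#'   `expected`, `observed`, `pass`). Fails with an error naming the first
#'   failing check if any fixture has drifted.
#' @export
validate_fixtures <- function() {
  t1 <- load_fixture("TABLE1")
  t2 <- load_fixture("TABLE2")
  bp <- load_fixture("BP_TARGETS")
  nd <- load_fixture("UNDRUGGABLE_TARGETS")
  tissue_ok <- all(unlist(c(t1$twas, t1$eqtl)) %in% .af_score_tissues)
  level_ok <- all(t2$max_level %in% names(.af_level_rank))
  effect_ok <- all(t2$overall_effect %in% .af_effects)
  checks <- data.frame(
    check = c("table1_rows", "table1_unique_symbols", "table1_tissues_valid",
              "table2_rows", "table2_levels_valid", "table2_effects_valid",
              "table2_guideline_rows", "table2_observational_rows",
              "bp_list_genes", "undruggable_list_genes"),
    expected = c(68, 1, 1, 72, 1, 1, 21, 15, 31, 12),
    observed = c(nrow(t1), as.integer(!anyDuplicated(t1$hgnc_symbol)),
                 as.integer(tissue_ok), nrow(t2), as.integer(level_ok),
                 as.integer(effect_ok),
                 sum(t2$max_level == "GUIDELINE"),
                 sum(t2$max_level == "OBSERVATIONAL"),
                 length(bp), length(nd)),
    stringsAsFactors = FALSE
  )
  checks$pass <- checks$expected == checks$observed
  if (!all(checks$pass)) {
    bad <- checks[!checks$pass, ]
    stop("fixture drift: ", paste(sprintf("%s (expected %s, got %s)",
                                          bad$check, bad$expected,
                                          bad$observed), collapse = "; "))
  }
  invisible(checks)
}
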