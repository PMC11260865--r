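test_that("a fully crossed drug-target world yields every link", {
  reg <- make_registry(sprintf("GENE%02d", 1:3),
                       target_class = rep("Ion channel", 3))
  drugs <- make_drugs(sprintf("drug%02d", 1:10))
  mech <- do.call(rbind, lapply(drugs$drug_id, function(d) {
    make_mechanisms(d, reg$ensembl_id)
  }))
  links <- join_targets_to_drugs(reg, mech, drugs)
  expect_identical(nrow(links), 30L)
  expect_true(all(links$ensembl_id %in% reg$ensembl_id))
  expect_identical(nrow(attr(links, "undrugged")), 0L)
})

test_that("targets without mechanisms are reported as undrugged", {
  reg <- make_registry(c("GENEA", "GENEB"))
  drugs <- make_drugs("druga")
  mech <- make_mechanisms(drugs$drug_id, reg$ensembl_id[1])
  links <- join_targets_to_drugs(reg, mech, drugs)
  expect_identical(nrow(links), 1L)
  expect_identical(attr(links, "undrugged")$hgnc_symbol, "GENEB")
})

test_that("mechanisms naming unknown drugs are a dangling-reference error", {
  reg <- make_registry("GENEA")
  drugs <- make_drugs("druga")
  mech <- make_mechanisms("NOSUCHDRUG", reg$ensembl_id)
  expect_error(join_targets_to_drugs(reg, mech, drugs),
               "dangling-reference.*NOSUCHDRUG")
})

test_that("salt formulations collapse to one parent drug", {
  lex <- load_fixture("SALT_LEXICON")
  wl <- load_fixture("CONJUGATE_WHITELIST")
  drugs <- make_drugs(c("Metoprolol Tartrate", "metoprolol succinate",
                        "Bisoprolol"))
  parents <- deduplicate_drugs(drugs, lex, wl)
  expect_identical(nrow(parents), 2L)
  metoprolol <- parents[parents$parent_drug_key == "metoprolol", ]
  expect_identical(metoprolol$n_members, 2L)
  # membership partitions the input
  membership <- attr(parents, "membership")
  expect_setequal(membership$drug_id, drugs$drug_id)
  expect_identical(sum(parents$n_members), nrow(drugs))
})

test_that("two-moiety conjugates stay distinct while PK salts merge", {
  lex <- load_fixture("SALT_LEXICON")
  wl <- load_fixture("CONJUGATE_WHITELIST")
  drugs <- make_drugs(c("Trastuzumab Emtansine", "trastuzumab"))
  parents <- deduplicate_drugs(drugs, lex, wl)
  expect_identical(nrow(parents), 2L)
  # stacked trailing salt tokens are stripped repeatedly
  expect_identical(parent_drug_key("beclomethasone dipropionate monohydrate",
                                   lex, wl),
                   "beclomethasone")
})

test_that("deduplication is idempotent and order-invariant", {
  lex <- load_fixture("SALT_LEXICON")
  wl <- load_fixture("CONJUGATE_WHITELIST")
  drugs <- make_drugs(c("ab hydrochloride", "ab tartrate", "cd", "ef sodium"))
  base <- deduplicate_drugs(drugs, lex, wl)
  # idempotent: keys are fixed points
  expect_identical(parent_drug_key(base$parent_drug_key, lex, wl),
                   base$parent_drug_key)
  for (seed in 1:5) {
    set.seed(seed)
    shuffled <- drugs[sample(nrow(drugs)), ]
    got <- deduplicate_drugs(shuffled, lex, wl)
    attr(got, "membership") <- NULL
    want <- base
    attr(want, "membership") <- NULL
    expect_identical(got, want)
  }
})

test_that("a planted salt-form partition is recovered exactly", {
  w <- generate_world(generator_config(seed = 5, n_genes = 30,
                                       n_parent_drugs = 25,
                                       salt_form_probs = c("1" = 0.4,
                                                           "2" = 0.4,
                                                           "3" = 0.2)))
  parents <- deduplicate_drugs(w$drugs, w$salt_lexicon,
                               w$conjugate_whitelist)
  expect_setequal(parents$parent_drug_key, w$truth$parent_names)
  membership <- attr(parents, "membership")
  truth <- w$truth$parent_partition
  expect_identical(
    membership$parent_drug_key[order(membership$drug_id)],
    truth$parent_drug_key[order(truth$drug_id)])
})

test_that("indication decoding removes DailyMed rows and flags unmapped", {
  map <- data.frame(ontology_term = c("OT:1", "OT:2"),
                    specialty = c("CARDIOLOGY", "RESPIRATORY"),
                    secondary = c("", ""), decoded_label = c("c", "r"))
  ind <- data.frame(
    drug_id = sprintf("D%02d", 1:12),
    ontology_term = c(rep("OT:1", 6), rep("OT:2", 4), "OT:9", "OT:9"),
    decoded_label = "", specialty = "", secondary = "",
    evidence_source = c(rep("TRIAL", 4), rep("DAILYMED", 4),
                        rep("ATC", 4)),
    stringsAsFactors = FALSE)
  out <- decode_indications(ind, map)
  expect_identical(nrow(out), 8L)
  expect_false(any(out$evidence_source == "DAILYMED"))
  expect_identical(sum(out$specialty == "UNMAPPED"), 2L)
  expect_identical(attr(out, "unmapped"), "OT:9")
  # identity case
  empty <- decode_indications(ind[0, ], map)
  expect_identical(nrow(empty), 0L)
})

test_that("search queries follow the structured template, two per drug", {
  q <- build_search_queries("ranolazine")
  expect_identical(q$query[q$source == "MEDLINE"],
                   '"ranolazine" AND "atrial fibrillation"')
  expect_identical(nrow(q), 2L)
  # duplicated member names collapse before query construction
  q2 <- build_search_queries(c("amiodarone", "Amiodarone ", "amiodarone"))
  expect_identical(sum(q2$source == "MEDLINE"), 2L)
  # the published arithmetic: 613 parent drugs, two sources, 1226 records
  q3 <- build_search_queries(sprintf("drug%03d", 1:613))
  expect_identical(nrow(q3), 1226L)
  expect_error(build_search_queries(character(0)), "non-empty")
  expect_error(build_search_queries(""), "non-empty")
})
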