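test_that("the indication adjacency matrix counts drug co-occurrence", {
  # one drug, one category
  one <- indication_adjacency(data.frame(drug_id = "a",
                                         specialty = "CARDIOLOGY"))
  expect_identical(one$matrix, matrix(1L, 1, 1,
                                      dimnames = list("CARDIOLOGY",
                                                      "CARDIOLOGY")))
  # pairwise enumeration: A:{cardio}, B:{cardio, resp}
  ind <- data.frame(drug_id = c("a", "b", "b"),
                    specialty = c("CARDIOLOGY", "CARDIOLOGY",
                                  "RESPIRATORY"))
  adj <- indication_adjacency(ind)
  m <- as.matrix(adj)
  expect_identical(m["CARDIOLOGY", "CARDIOLOGY"], 2L)
  expect_identical(m["CARDIOLOGY", "RESPIRATORY"], 1L)
  expect_identical(m["RESPIRATORY", "RESPIRATORY"], 1L)
  # repeated trial records of the same drug-category pair count once
  dup <- rbind(ind, ind)
  expect_identical(as.matrix(indication_adjacency(dup)), m)
  # empty input gives a 0-dimension matrix
  empty <- indication_adjacency(ind[0, ])
  expect_identical(dim(empty$matrix), c(0L, 0L))
})

test_that("adjacency symmetry and diagonal bounds hold on random worlds", {
  for (seed in 1:5) {
    w <- generate_world(generator_config(seed = seed, n_genes = 20,
                                         n_parent_drugs = 15))
    decoded <- decode_indications(w$indications, w$ontology_map)
    parents <- deduplicate_drugs(w$drugs, w$salt_lexicon,
                                 w$conjugate_whitelist)
    m <- as.matrix(indication_adjacency(decoded,
                                        attr(parents, "membership")))
    expect_identical(m, t(m))
    d <- diag(m)
    for (i in seq_along(d)) for (j in seq_along(d)) {
      expect_lte(m[i, j], min(d[i], d[j]))
    }
    # category order: descending diagonal, ties alphabetical
    expect_identical(order(-d, rownames(m)), seq_along(d))
  }
})

test_that("the action tree keeps only high-priority drugs", {
  reg <- make_registry(c("GENEA", "GENEB"),
                       target_class = c("Ion channel", "Enzyme"))
  drugs <- make_drugs(c("druga", "drugb"))
  mech <- rbind(make_mechanisms(drugs$drug_id[1], reg$ensembl_id[1]),
                make_mechanisms(drugs$drug_id[2], reg$ensembl_id[2]))
  links <- join_targets_to_drugs(reg, mech, drugs)
  scores <- data.frame(symbol = c("GENEA", "GENEB"),
                       gene_priority = c(TRUE, FALSE))
  tree <- action_dendrogram(links, scores)
  expect_identical(tree$n_leaves, 1L)
  expect_named(tree$children, "INHIBITOR")
  # no high-priority targets: empty tree
  none <- action_dendrogram(links, data.frame(symbol = "GENEA",
                                              gene_priority = FALSE))
  expect_identical(none$n_leaves, 0L)
  expect_length(none$children, 0)
  expect_identical(tree_to_newick(none), "();")
})

test_that("a planted inhibitor set shapes the dendrogram exactly", {
  channels <- make_registry(sprintf("CHAN%02d", 1:3),
                            target_class = rep("Ion channel", 3))
  drugs <- make_drugs(sprintf("inh%02d", 1:10))
  mech <- do.call(rbind, lapply(seq_len(10), function(i) {
    make_mechanisms(drugs$drug_id[i],
                    channels$ensembl_id[(i %% 3) + 1], "inhibitor")
  }))
  links <- join_targets_to_drugs(channels, mech, drugs)
  scores <- data.frame(symbol = channels$hgnc_symbol, gene_priority = TRUE)
  tree <- action_dendrogram(links, scores)
  expect_identical(tree$n_leaves, 10L)
  expect_identical(unname(tree$leaf_counts["INHIBITOR"]), 10L)
  inhibitor <- tree$children$INHIBITOR$children$`Ion channel`
  expect_length(inhibitor$children, 3)
  expect_identical(tree$inhibitor_share, 1)
  # leaf multiset equals the filtered link multiset
  leaves <- unlist(lapply(inhibitor$children, `[[`, "drugs"))
  expect_setequal(leaves, drugs$name)
})

test_that("trait partition is exhaustive and sums to the drugged targets", {
  profiles <- rbind(
    make_profile("A", traits = "AF"),
    make_profile("B", traits = "AF"),
    make_profile("C", traits = c("AF", "PR_INDICES")),
    make_profile("D", traits = "LA_INDICES"),
    make_profile("E", traits = character(0), tissues = "LV")
  )
  cells <- partition_by_trait(profiles)
  expect_identical(unname(cells["AF"]), 2L)
  expect_identical(unname(cells["AF+PR_INDICES"]), 1L)
  expect_identical(unname(cells["LA_INDICES"]), 1L)
  expect_identical(unname(cells["NONE"]), 1L)
  expect_identical(sum(cells), nrow(profiles))
  # restricted to drugged targets via links
  links <- data.frame(hgnc_symbol = c("A", "C"))
  cells2 <- partition_by_trait(profiles, links)
  expect_identical(sum(cells2), 2L)
})

test_that("the planted trait partition is recovered from synthetic worlds", {
  w <- generate_world(generator_config(seed = 21, n_genes = 60,
                                       n_parent_drugs = 15))
  run <- run_pipeline(w)
  truth <- w$truth$gene_patterns
  drugged <- truth[truth$symbol %in% run$links$hgnc_symbol &
                     truth$symbol %in% run$profiles$symbol, ]
  want <- partition_by_trait(
    data.frame(symbol = drugged$symbol, traits = drugged$traits))
  got <- partition_by_trait(run$profiles, run$links)
  expect_identical(got, want)
  expect_identical(sum(got),
                   length(intersect(run$links$hgnc_symbol,
                                    run$profiles$symbol)))
})
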