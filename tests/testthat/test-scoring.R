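# Independent brute-force oracles: the scoring rules re-stated as explicit
# case analysis, kept separate from the package's arithmetic.

oracle_sm <- function(family, pocket) {
  pts <- 0L
  if (family) pts <- pts + 1L
  if (!is.na(pocket)) {
    if (pocket >= 0.7) pts <- pts + 1L        # high-quality pocket
    else if (pocket > 0) pts <- pts + 1L      # medium-quality pocket
  }
  pts
}

oracle_prior <- function(traits, tissues, rvas) {
  length(intersect(traits, c("AF", "PR_INDICES", "LA_INDICES"))) +
    length(intersect(tissues, c("LA", "RA", "LV"))) + as.integer(rvas)
}

test_that("small-molecule score matches enumeration over the boundary grid", {
  grid <- expand.grid(family = c(TRUE, FALSE),
                      pocket = c(NA, 0, 0.3, 0.7, 1.0))
  got <- small_molecule_score(grid$family, grid$pocket)
  want <- mapply(oracle_sm, grid$family, grid$pocket)
  expect_identical(got, as.integer(want))
  # spot values forced by the rule
  expect_identical(small_molecule_score(TRUE, 0.9), 2L)
  expect_identical(small_molecule_score(FALSE, NA), 0L)
  expect_identical(small_molecule_score(TRUE, 0.3), 2L)
  expect_identical(small_molecule_score(TRUE, 0.0), 1L)
  expect_error(small_molecule_score(TRUE, 1.2), "pocket_score")
})

test_that("antibody score and priority match enumeration of all 8 flag sets", {
  flags <- expand.grid(uniprot = c(TRUE, FALSE), go = c(TRUE, FALSE),
                       hpa = c(TRUE, FALSE))
  got <- antibody_score(flags$uniprot, flags$go, flags$hpa)
  want <- rowSums(flags)
  expect_identical(got, as.integer(want))
  # the > 1 rule: two accessibility sources suffice, one does not
  tr <- make_tractability(sprintf("SYNG%05d", 1:2),
                          uniprot = c(TRUE, FALSE), go = c(TRUE, FALSE),
                          hpa = c(FALSE, TRUE))
  ds <- druggability_scores(tr)
  expect_identical(ds$ab_score, c(2L, 1L))
  expect_identical(ds$druggability_priority, c(TRUE, FALSE))
})

test_that("druggability priority matches enumeration over both domains", {
  grid <- expand.grid(family = c(TRUE, FALSE),
                      pocket = c(NA, 0, 0.3, 0.7, 1.0),
                      uniprot = c(TRUE, FALSE), go = c(TRUE, FALSE),
                      hpa = c(TRUE, FALSE))
  tr <- make_tractability(sprintf("SYNG%05d", seq_len(nrow(grid))),
                          family = grid$family, pocket = grid$pocket,
                          uniprot = grid$uniprot, go = grid$go,
                          hpa = grid$hpa)
  ds <- druggability_scores(tr)
  want <- mapply(function(f, p, u, g, h) {
    oracle_sm(f, p) > 1 || sum(u, g, h) > 1
  }, grid$family, grid$pocket, grid$uniprot, grid$go, grid$hpa)
  expect_identical(ds$druggability_priority, unname(want))
})

test_that("prioritisation score reproduces the published worked examples", {
  profiles <- rbind(
    make_profile("KCNJ5", traits = "AF", tissues = c("RA", "LA", "LV")),
    make_profile("ADRA1A", traits = "AF"),
    make_profile("NR3C1", traits = "AF", tissues = "LV")
  )
  sc <- prioritisation_score(profiles)
  kcnj5 <- sc[sc$symbol == "KCNJ5", ]
  expect_gte(kcnj5$prioritisation_score, 4L)
  expect_true(kcnj5$gene_priority)
  # the doxazosin target scores 1 and is not prioritised
  adra1a <- sc[sc$symbol == "ADRA1A", ]
  expect_identical(adra1a$prioritisation_score, 1L)
  expect_false(adra1a$gene_priority)
  # one trait plus LV expression evidence crosses the > 1 bar
  nr3c1 <- sc[sc$symbol == "NR3C1", ]
  expect_identical(nr3c1$prioritisation_score, 2L)
  expect_true(nr3c1$gene_priority)
})

test_that("prioritisation equals the set-cardinality oracle on random profiles", {
  set.seed(42)
  traits_all <- c("AF", "PR_INDICES", "LA_INDICES")
  tissues_all <- c("LA", "RA", "LV")
  for (i in 1:200) {
    traits <- sample(traits_all, sample(0:3, 1))
    tissues <- sample(tissues_all, sample(0:3, 1))
    rvas <- sample(c(TRUE, FALSE), 1)
    sc <- prioritisation_score(make_profile("G", traits, tissues, rvas))
    want <- oracle_prior(traits, tissues, rvas)
    expect_identical(sc$prioritisation_score, want)
    expect_identical(sc$gene_priority, want > 1)
    expect_lte(sc$prioritisation_score, 7L)
  }
})

test_that("scores never decrease when evidence is added", {
  set.seed(7)
  traits_all <- c("AF", "PR_INDICES", "LA_INDICES")
  tissues_all <- c("LA", "RA", "LV")
  for (i in 1:50) {
    traits <- sample(traits_all, sample(0:2, 1))
    tissues <- sample(tissues_all, sample(0:2, 1))
    base <- prioritisation_score(
      make_profile("G", traits, tissues, FALSE))$prioritisation_score
    grown <- list(
      make_profile("G", union(traits, sample(traits_all, 1)), tissues, FALSE),
      make_profile("G", traits, union(tissues, sample(tissues_all, 1)), FALSE),
      make_profile("G", traits, tissues, TRUE)
    )
    for (g in grown) {
      expect_gte(prioritisation_score(g)$prioritisation_score, base)
    }
  }
})

test_that("ranking is descending with alphabetical tie-break, order-invariant", {
  profiles <- rbind(
    make_profile("ZZB", traits = c("AF", "PR_INDICES", "LA_INDICES")),
    make_profile("AAA", traits = "AF"),
    make_profile("BBB", traits = c("AF", "PR_INDICES"))
  )
  sc <- prioritisation_score(profiles)
  expect_identical(rank_targets(sc)$symbol, c("ZZB", "BBB", "AAA"))
  # ties break alphabetically
  tie <- prioritisation_score(rbind(make_profile("BETA", traits = "AF"),
                                    make_profile("ALPHA", traits = "AF")))
  expect_identical(rank_targets(tie)$symbol, c("ALPHA", "BETA"))
  for (seed in 1:5) {
    set.seed(seed)
    shuffled <- sc[sample(nrow(sc)), ]
    expect_identical(rank_targets(shuffled), rank_targets(sc))
  }
})

test_that("score components respect their bounds on random tractability", {
  set.seed(99)
  n <- 100
  tr <- make_tractability(
    sprintf("SYNG%05d", 1:n),
    family = sample(c(TRUE, FALSE), n, TRUE),
    pocket = ifelse(runif(n) < 0.3, NA, round(runif(n), 2)),
    uniprot = sample(c(TRUE, FALSE), n, TRUE),
    go = sample(c(TRUE, FALSE), n, TRUE),
    hpa = sample(c(TRUE, FALSE), n, TRUE))
  ds <- druggability_scores(tr)
  expect_true(all(ds$sm_score >= 0 & ds$sm_score <= 2))
  expect_true(all(ds$ab_score >= 0 & ds$ab_score <= 3))
})
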