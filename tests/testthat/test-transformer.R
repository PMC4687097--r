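test_that("site enumeration reproduces the case-study counts", {
  sb <- enumerate_sites(fixture_mol("bisphenol_a"))
  expect_equal(nrow(sb), 17L)
  expect_equal(length(unique(sb$symmetry_class)), 7L)
  sp <- enumerate_sites(fixture_mol("pcb3"))
  expect_equal(nrow(sp), 13L)
  expect_equal(length(unique(sp$symmetry_class)), 8L)
})

test_that("benzene collapses to a single symmetry class", {
  s <- enumerate_sites(benzene())
  expect_equal(nrow(s), 6L)
  expect_equal(length(unique(s$symmetry_class)), 1L)
  expect_equal(s$atom[s$representative], 1L)   # lowest-index representative
})

test_that("matching is exact on all three key fields", {
  tabs <- curated_tables()
  ac <- fixture_mol("acetaminophen")
  sites <- enumerate_sites(ac)
  m <- match_sites(sites, tabs$phase1)
  atoms <- vapply(m, `[[`, integer(1), "atom")
  expect_true(11L %in% atoms)    # the phenolic-oxygen site matches
  # empty table matches nothing
  empty <- filter_rules(tabs, "no-such-record")
  expect_equal(length(match_sites(sites, empty$phase1)), 0L)
})

test_that("fallback-typed sites never match", {
  lone <- molgraph("C", NULL)     # types as C?
  s <- enumerate_sites(lone)
  expect_equal(length(match_sites(s, curated_tables()$phase1)), 0L)
})

test_that("a hydroxylation rule turns benzene into phenol", {
  b <- benzene()
  rec <- reaction_record("benz_oh", "2E1", "I", b, edit_hydroxylation(b, 1L)$product)
  tabs <- build_tables(list(rec))
  prods <- predict_metabolites(b, tabs, phases = "I", depth = 1L)
  expect_equal(length(prods), 1L)
  expect_isomorphic(prods[[1]]$graph, phenol_graph())
})

test_that("acetaminophen yields its three published metabolites", {
  prods <- predict_metabolites(fixture_mol("acetaminophen"), curated_tables())
  has <- function(target) any(vapply(prods, function(p)
    graph_isomorphic(p$graph, target), logical(1)))
  expect_true(has(fixture_mol("napqi")))
  expect_true(has(fixture_mol("acetaminophen_glucuronide")))
  expect_true(has(fixture_mol("acetaminophen_sulfate")))
  # the conjugates arise at the phenolic oxygen, atom 11
  smry <- products_summary(prods)
  conj <- smry$site[smry$phase_chain == "II"]
  expect_true(all(conj == 11L))
})

test_that("the BPA panel is exactly the seven unique derivatives", {
  prods <- predict_metabolites(fixture_mol("bisphenol_a"), bpa_panel_tables())
  expect_equal(length(prods), 7L)
  expected <- lapply(bpa_expected_smiles, read_smiles)
  for (nm in names(expected)) {
    expect_true(any(vapply(prods, function(p)
      graph_isomorphic(p$graph, expected[[nm]]), logical(1))),
      info = paste("missing BPA derivative:", nm))
  }
  # every product differs from the query
  qk <- canonical_key(fixture_mol("bisphenol_a"))
  expect_false(qk %in% vapply(prods, function(p) p$canonical, character(1)))
})

test_that("symmetric sites yield one product and output order is stable", {
  prods1 <- predict_metabolites(fixture_mol("bisphenol_a"), bpa_panel_tables())
  prods2 <- predict_metabolites(fixture_mol("bisphenol_a"), bpa_panel_tables())
  expect_identical(products_summary(prods1), products_summary(prods2))
  # hydroxylation fires once although four ring positions share the class
  smry <- products_summary(prods1)
  expect_equal(sum(smry$rule_provenance == "bpa_hydroxylation"), 1L)
})

test_that("phases and depth configuration are honored", {
  bpa <- fixture_mol("bisphenol_a")
  tabs <- bpa_panel_tables()
  p1 <- predict_metabolites(bpa, tabs, phases = "I", depth = 1L)
  expect_true(all(vapply(p1, function(x)
    identical(x$phase_chain, "I"), logical(1))))
  p2 <- predict_metabolites(bpa, tabs, phases = c("I", "II"), depth = 1L)
  expect_false(any(vapply(p2, function(x)
    identical(x$phase_chain, c("I", "II")), logical(1))))
  expect_equal(length(predict_metabolites(benzene(), tabs)), 0L)
})

test_that("valence-violating grafts reject the product, not the run", {
  # force a hydroxylation rule onto a site whose hydrogen is already gone:
  # apply_rule returns NULL rather than erroring
  b <- benzene()
  rec <- reaction_record("benz_oh", "2E1", "I", b, edit_hydroxylation(b, 1L)$product)
  rule <- build_tables(list(rec))$phase1$entries[[1]]$rules[[1]]
  rule$pattern$atoms$h_p[1] <- -1L    # corrupt the hydrogen delta
  expect_null(apply_rule(b, 1L, rule))
})
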