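test_that("neighborhood keys match the printed worked examples", {
  ap <- fixture_mol("antipyrine")
  k <- extract_key(ap, assign_types(ap), 9L)
  expect_equal(k$rc, "C1a")
  expect_equal(k$adjacent, "C8y")
  expect_equal(k$distant, sort(c("C1a", "C8x", "N4y")))

  ac <- fixture_mol("acetaminophen")
  k2 <- extract_key(ac, assign_types(ac), 11L)
  expect_equal(k2$rc, "O1a")
  expect_equal(k2$adjacent, "C8y")
  expect_equal(k2$distant, sort(c("C8x", "C8x", "O1a")))
})

test_that("an isolated atom keys as itself with empty adjacency", {
  lone <- molgraph("O", NULL)
  k <- extract_key(lone, "O1a", 1L)   # type supplied directly
  expect_equal(k$adjacent, character(0))
  expect_equal(k$distant, "O1a")
})

test_that("reaction centers are the aligned atoms whose type changes", {
  ap <- fixture_mol("antipyrine"); hp <- fixture_mol("hydroxymethylantipyrine")
  a <- max_common_subgraph(ap, hp)
  expect_equal(find_reaction_centers(a, assign_types(ap), assign_types(hp)), 9L)
  # identity pair has no centers
  a2 <- max_common_subgraph(ap, ap)
  expect_equal(find_reaction_centers(a2, assign_types(ap), assign_types(ap)),
               integer(0))
  # benzene -> phenol: the hydroxylated carbon
  b <- benzene(); ph <- edit_hydroxylation(b, 1L)$product
  a3 <- max_common_subgraph(b, ph)
  expect_equal(find_reaction_centers(a3, assign_types(b), assign_types(ph)), 1L)
})

test_that("the antipyrine rule stores a hydroxyl addition at the center", {
  rec <- reaction_record("antipyrine", "CYP3A4", "I", fixture_mol("antipyrine"),
                         fixture_mol("hydroxymethylantipyrine"))
  res <- extract_rule(rec, 9L)
  expect_equal(res$rule$product_rc_type, "C1b")
  expect_equal(res$rule$fragment$atoms$element, "O")
  expect_equal(res$rule$fragment$attach$patom, 1L)   # attaches to the center
  expect_equal(res$rule$enzymes, "3A4")              # CYP prefix normalized
  expect_error(extract_rule(rec, 2L), "not a reaction center")
})

test_that("demethylation rules record the leaving methyl", {
  recs <- generate_synthetic_reactions(31, 60)
  demeth <- Filter(function(r) attr(r, "kind") == "dealkylation", recs)
  expect_gt(length(demeth), 0)
  rec <- demeth[[1]]
  res <- extract_rule(rec, attr(rec, "center"))
  expect_equal(nrow(res$rule$fragment$atoms), 0L)
  expect_equal(sum(res$rule$pattern$atoms$removed), 1L)
  expect_equal(res$rule$pattern$atoms$element[res$rule$pattern$atoms$removed], "C")
})

test_that("build_tables indexes the antipyrine key and rejects empty input", {
  expect_error(build_tables(list()), "no reaction records")
  rec <- reaction_record("antipyrine", "3A4", "I", fixture_mol("antipyrine"),
                         fixture_mol("hydroxymethylantipyrine"))
  tabs <- build_tables(list(rec))
  ks <- key_string(structure(list(rc = "C1a", adjacent = "C8y",
                                  distant = sort(c("C1a", "C8x", "N4y"))),
                             class = "lookup_key"))
  expect_true(ks %in% names(tabs$phase1$entries))
  expect_equal(length(tabs$phase2$entries), 0L)
})

test_that("rules round-trip: applying a mined rule regenerates its product", {
  recs <- generate_synthetic_reactions(77, 40)
  for (rec in recs) {
    tabs <- build_tables(list(rec))
    prods <- predict_metabolites(rec$reactant, tabs, phases = rec$phase,
                                 depth = 1L)
    expect_gte(length(prods), 1L)
    for (p in prods) expect_isomorphic(p$graph, rec$product)
  }
})

test_that("multi-center reactions yield one entry per center", {
  bpa <- fixture_mol("bisphenol_a")
  rec <- reaction_record("dienone", "2E1", "I", bpa,
                         edit_hydroxyl_to_carbonyl(bpa, 7L)$product)
  tabs <- build_tables(list(rec))
  a <- max_common_subgraph(rec$reactant, rec$product)
  centers <- find_reaction_centers(a, assign_types(rec$reactant),
                                   assign_types(rec$product))
  n_rules <- sum(vapply(tabs$phase1$entries, function(e) length(e$rules),
                        integer(1)))
  expect_equal(n_rules + nrow(tabs$diagnostics), length(centers))
})

test_that("tables serialize losslessly and deterministically", {
  recs <- generate_synthetic_reactions(5, 8)
  tabs <- build_tables(recs)
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  save_tables(tabs, f1)
  reloaded <- load_tables(f1)
  save_tables(reloaded, f2)
  expect_identical(readLines(f1), readLines(f2))
  # re-building from the same records gives byte-identical files
  f3 <- tempfile(fileext = ".json")
  save_tables(build_tables(recs), f3)
  expect_identical(readLines(f1), readLines(f3))
  expect_identical(sort(names(reloaded$phase1$entries)),
                   sort(names(tabs$phase1$entries)))
  # reloaded rules still apply
  prods <- predict_metabolites(recs[[1]]$reactant, reloaded,
                               phases = recs[[1]]$phase, depth = 1L)
  expect_gte(length(prods), 1L)
})

test_that("corrupt or mismatched table files are rejected", {
  f <- tempfile(fileext = ".json")
  writeLines('{"schema": 99, "phase1": {}, "phase2": {}}', f)
  expect_error(load_tables(f), "schema version")
  writeLines('{"schema": 1, "phase1', f)   # truncated
  expect_error(load_tables(f), "parse")
})

test_that("enzyme names normalize to subfamily tokens and EC numbers", {
  expect_equal(normalize_enzyme(c("CYP3A4", "cyp2e1", "3A4")),
               c("3A4", "2E1", "3A4"))
  expect_equal(normalize_enzyme(c("UGT", "SULT", "GST", "COMT")),
               c("2.4.1.17", "2.8.2.1", "2.5.1.18", "2.1.1.6"))
})
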