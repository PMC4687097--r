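test_that("the synthetic generator is deterministic and respects n", {
  expect_equal(generate_synthetic_reactions(42, 0), list())
  r1 <- generate_synthetic_reactions(42, 20)
  r2 <- generate_synthetic_reactions(42, 20)
  expect_equal(length(r1), 20L)
  key <- function(recs) vapply(recs, function(r)
    paste(r$id, attr(r, "kind"), attr(r, "center"),
          canonical_key(r$reactant), canonical_key(r$product)), character(1))
  expect_identical(key(r1), key(r2))
})

test_that("every edit kind occurs among 200 seeded records", {
  recs <- generate_synthetic_reactions(1, 200)
  kinds <- vapply(recs, attr, character(1), "kind")
  expect_setequal(unique(kinds),
                  c("hydroxylation", "epoxidation", "dealkylation",
                    "hydroxyl_to_carbonyl", "glucuronidation", "sulfation",
                    "methylation", "acetylation", "glutathione"))
})

test_that("edit functions produce valence-consistent products", {
  recs <- generate_synthetic_reactions(9, 30)
  for (rec in recs) {
    expect_true(isTRUE(proximal:::.check_valences(rec$product)),
                info = rec$id)
    expect_false(canonical_key(rec$reactant) == canonical_key(rec$product),
                 info = rec$id)
  }
})

test_that("curated tables cover the named transformation chemistry", {
  tabs <- curated_tables()
  provs <- unlist(lapply(c(tabs$phase1$entries, tabs$phase2$entries),
                         function(e) lapply(e$rules, function(r)
                           strsplit(r$provenance, ";")[[1]])))
  expect_true(all(c("bpa_hydroxylation", "bpa_epoxide", "bpa_carbonyl",
                    "phenol_glucuronide", "phenol_sulfate",
                    "catechol_methylation", "epoxide_glutathione",
                    "n_demethylation") %in% provs))
  # enzyme annotations from the published score tables
  e1 <- tabs$phase1$entries
  hydrox <- NULL
  for (e in e1) for (r in e$rules)
    if (grepl("bpa_hydroxylation", r$provenance)) hydrox <- r
  expect_equal(hydrox$enzymes, c("1A1", "1A2", "1B1", "3A4"))
})

test_that("curated rules round-trip onto their exemplar reactions", {
  tabs <- curated_tables()
  for (rec in tabs$records[1:8]) {
    prods <- predict_metabolites(rec$reactant,
                                 filter_rules(tabs, rec$id),
                                 phases = rec$phase, depth = 1L)
    expect_true(any(vapply(prods, function(p)
      graph_isomorphic(p$graph, rec$product), logical(1))),
      info = rec$id)
  }
})

test_that("curated tables survive a save/load round trip unchanged", {
  tabs <- curated_tables()
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  save_tables(tabs, f1)
  save_tables(load_tables(f1), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("packaged fragment library parses into valid subgraphs", {
  fr <- load_fragments()
  expect_true(all(c("glucuronosyl", "sulfo", "glutathionyl", "acetyl",
                    "methyl") %in% names(fr)))
  expect_equal(nrow(fr$glucuronosyl$atoms), 12L)
  expect_equal(nrow(fr$glutathionyl$atoms), 20L)
  # grafting glucuronosyl onto phenol gives phenyl glucuronide
  ph <- phenol_graph()
  g <- edit_glucuronidation(ph, 7L)$product
  expect_equal(mol_formula(g), "C12H14O7")
  expect_true(isTRUE(proximal:::.check_valences(g)))
})

test_that("the demo produces ranked case-study tables", {
  out <- proximal_demo(quiet = TRUE)
  expect_named(out, c("bisphenol_a", "pcb3"))
  expect_gt(nrow(out$bisphenol_a$summary), 0)
  expect_gt(nrow(out$pcb3$summary), 0)
  rk <- out$pcb3$ranking
  expect_equal(rk$rank, seq_len(nrow(rk)))
  expect_true(!is.unsorted(-rk$score_full))
})
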