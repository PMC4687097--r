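test_that("antipyrine aligns fully with its hydroxymethyl product", {
  ap <- fixture_mol("antipyrine")
  hp <- fixture_mol("hydroxymethylantipyrine")
  a <- max_common_subgraph(ap, hp)
  expect_equal(a$score, 14L)
  expect_true(all(a$pairs[, 1] == a$pairs[, 2]))
  tab <- alignment_table(a, ap, hp)
  differs <- tab$reactant_type != tab$product_type
  expect_equal(tab$reactant_index[differs], 9L)
  expect_equal(tab$reactant_type[differs], "C1a")
  expect_equal(tab$product_type[differs], "C1b")
})

test_that("a molecule aligns to itself with the identity", {
  for (g in list(benzene(), fixture_mol("acetaminophen"))) {
    a <- max_common_subgraph(g, g)
    expect_equal(a$score, nrow(g$atoms))
    expect_true(all(a$pairs[, 1] == a$pairs[, 2]))
  }
})

test_that("only the shared fragment of C-C-O and C-C-N aligns", {
  g1 <- molgraph(c("C", "C", "O"), data.frame(i = 1:2, j = 2:3, order = 1))
  g2 <- molgraph(c("C", "C", "N"), data.frame(i = 1:2, j = 2:3, order = 1))
  a <- max_common_subgraph(g1, g2)
  expect_equal(a$score, 2L)
  expect_equal(brute_force_mcs(g1, g2)$score, 2L)
})

test_that("brute-force oracle handles ring embeddings and disjoint elements", {
  c6 <- carbon_ring(6); c5 <- carbon_ring(5)
  expect_equal(brute_force_mcs(c6, c6)$score, 6L)
  expect_equal(brute_force_mcs(c6, c5)$score, 5L)
  expect_equal(brute_force_mcs(molgraph("C", NULL), molgraph("N", NULL))$score, 0L)
  big <- random_molecule(13)
  expect_error(brute_force_mcs(big, big), "12")
})

test_that("branch-and-bound matches the exhaustive oracle and is symmetric", {
  set.seed(7211)
  for (t in 1:60) {
    g1 <- random_molecule(sample(4:10, 1))
    g2 <- if (t %% 2 == 0) random_pair(sample(5:10, 1))[[2]]
          else random_molecule(sample(4:10, 1))
    s12 <- max_common_subgraph(g1, g2)$score
    expect_equal(s12, brute_force_mcs(g1, g2)$score,
                 info = paste("trial", t))
    expect_equal(s12, max_common_subgraph(g2, g1)$score,
                 info = paste("symmetry, trial", t))
  }
})

test_that("alignment recovers exactly the injected edit on synthetic pairs", {
  recs <- generate_synthetic_reactions(555, 25)
  for (rec in recs) {
    a <- max_common_subgraph(rec$reactant, rec$product)
    rt <- assign_types(rec$reactant); pt <- assign_types(rec$product)
    centers <- find_reaction_centers(a, rt, pt)
    expect_true(attr(rec, "center") %in% centers,
                info = paste(rec$id, attr(rec, "kind")))
    # unedited atoms align to themselves: reactant indices are stable
    # under the appended-atom edits of the generator
    nmin <- min(nrow(rec$reactant$atoms), a$score)
    expect_gte(a$score, nrow(rec$reactant$atoms) - 1L)  # at most one leaving methyl
  }
})

test_that("alignment pair lists are ordered by reactant atom index", {
  set.seed(12)
  for (t in 1:10) {
    pr <- random_pair(sample(5:9, 1))
    a <- max_common_subgraph(pr[[1]], pr[[2]])
    expect_true(!is.unsorted(a$pairs[, 1], strictly = TRUE))
  }
})
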