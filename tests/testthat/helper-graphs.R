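# Shared helpers: small molecule constructors and a seeded random-molecule
# generator used by the property-style tests.

benzene <- function(order = 1:6) {
  ring <- data.frame(i = 1:6, j = c(2:6, 1), order = c(2L, 1L, 2L, 1L, 2L, 1L))
  # re-label atoms according to `order` (a permutation of 1:6)
  perm <- match(1:6, order)
  b <- data.frame(i = perm[ring$i], j = perm[ring$j], order = ring$order)
  perceive_aromaticity(molgraph(rep("C", 6), b))
}

phenol_graph <- function() {
  perceive_aromaticity(molgraph(
    c(rep("C", 6), "O"),
    data.frame(i = c(1:6, 1), j = c(2:6, 1, 7),
               order = c(2L, 1L, 2L, 1L, 2L, 1L, 1L))))
}

cyclohexane <- function() {
  molgraph(rep("C", 6), data.frame(i = 1:6, j = c(2:6, 1), order = 1L))
}

carbon_ring <- function(n) {
  molgraph(rep("C", n), data.frame(i = seq_len(n), j = c(seq_len(n)[-1], 1),
                                   order = 1L))
}

# Seeded random connected molecule: tree plus an occasional ring-closing
# bond, elements C/N/O, degree-limited to stay molecule-like.
random_molecule <- function(n, ring_prob = 0.5) {
  els <- sample(c("C", "C", "C", "N", "O"), n, replace = TRUE)
  b <- data.frame(i = integer(0), j = integer(0), order = integer(0))
  for (v in seq_len(n)[-1]) {
    b <- rbind(b, data.frame(i = sample(v - 1L, 1), j = v, order = 1L))
  }
  if (n > 3 && stats::runif(1) < ring_prob) {
    e <- sort(sample(n, 2))
    if (e[1] != e[2] && !any(b$i == e[1] & b$j == e[2]))
      b <- rbind(b, data.frame(i = e[1], j = e[2], order = 1L))
  }
  molgraph(els, b)
}

# A random molecule plus a structurally related partner (atom/bond edits),
# mimicking reactant-product pairs.
random_pair <- function(n) {
  g1 <- random_molecule(n)
  els <- g1$atoms$element; b <- g1$bonds[, c("i", "j", "order")]
  if (stats::runif(1) < 0.5 && n > 4) {          # drop a leaf atom
    deg <- tabulate(c(b$i, b$j), n)
    leaf <- which(deg == 1L)
    if (length(leaf)) {
      drop <- leaf[sample(length(leaf), 1)]
      keep <- setdiff(seq_len(n), drop)
      remap <- match(seq_len(n), keep)
      b2 <- b[b$i != drop & b$j != drop, , drop = FALSE]
      b2$i <- remap[b2$i]; b2$j <- remap[b2$j]
      return(list(g1, molgraph(els[keep], b2)))
    }
  }
  els2 <- c(els, sample(c("C", "N", "O"), 1))    # add an atom
  b2 <- rbind(b, data.frame(i = sample(n, 1), j = n + 1L, order = 1L))
  list(g1, molgraph(els2, b2))
}

expect_isomorphic <- function(g1, g2) {
  expect_true(graph_isomorphic(g1, g2),
              info = sprintf("expected %s isomorphic to %s",
                             mol_formula(g1), mol_formula(g2)))
}

# expected BPA derivative structures, hand-written constitutionally and
# parsed through the SMILES route (independent of the rule machinery)
bpa_expected_smiles <- c(
  hydroxy      = "CC(C)(c1ccc(O)cc1)c1ccc(O)c(O)c1",
  dienone      = "CC(C)(c1ccc(O)cc1)C2C=CC(=O)C=C2",
  epoxide      = "CC(C)(c1ccc(O)cc1)C1=CC=C(O)C2OC12",
  glucuronide  = "CC(C)(c1ccc(O)cc1)c1ccc(OC2OC(C(=O)O)C(O)C(O)C2O)cc1",
  sulfate      = "CC(C)(c1ccc(O)cc1)c1ccc(OS(=O)(=O)O)cc1",
  oh_glucuronide = "CC(C)(c1ccc(O)cc1)c1ccc(O)c(OC2OC(C(=O)O)C(O)C(O)C2O)c1",
  oh_sulfate   = "CC(C)(c1ccc(O)cc1)c1ccc(O)c(OS(=O)(=O)O)c1"
)

# restricted curated table for the published BPA derivative panel
bpa_panel_tables <- function() {
  filter_rules(curated_tables(),
               c("bpa_hydroxylation", "bpa_carbonyl", "bpa_epoxide",
                 "phenol_glucuronide", "phenol_sulfate",
                 "hydroxybpa_glucuronide", "hydroxybpa_sulfate"))
}
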