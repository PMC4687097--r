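test_that("molfile read/write round trip preserves structure and atom order", {
  for (nm in c("antipyrine", "acetaminophen", "bisphenol_a", "pcb3",
               "acetaminophen_glucuronide")) {
    g <- fixture_mol(nm)
    g2 <- read_molfile(write_molfile(g))
    expect_identical(g2$atoms$element, g$atoms$element)
    expect_identical(g2$atoms$hcount, g$atoms$hcount)
    expect_identical(g2$bonds[, c("i", "j", "order")],
                     g$bonds[, c("i", "j", "order")])
    expect_isomorphic(g, g2)
  }
})

test_that("molfile parser reports malformed input with the offending line", {
  ok <- write_molfile(benzene())
  lines <- strsplit(ok, "\n")[[1]]
  # counts line declares more atoms than present
  bad <- lines
  bad[4] <- sub("  6  6", "  7  6", bad[4])
  expect_error(read_molfile(bad), "declares 7 atoms")
  # V3000 rejected
  bad <- lines; bad[4] <- "  0  0  0     0  0            999 V3000"
  expect_error(read_molfile(bad), "V3000")
  # unknown element symbol names its line
  bad <- lines; bad[5] <- sub(" C ", " Zz", bad[5])
  expect_error(read_molfile(bad), "unknown element.*line 5")
  # aromatic order-4 bonds are not a Kekule structure
  bad <- lines
  bad[11] <- paste0(substr(bad[11], 1, 6), "  4", substr(bad[11], 10, nchar(bad[11])))
  expect_error(read_molfile(bad), "order 4")
})

test_that("explicit hydrogens fold into implicit counts", {
  txt <- paste(c("methane-ish", "", "",
                 "  3  2  0  0  0  0  0  0  0  0999 V2000",
                 sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0", 0, 0, 0, c("C", "H", "H")),
                 "  1  2  1  0", "  1  3  1  0", "M  END"), collapse = "\n")
  g <- read_molfile(txt)
  expect_equal(nrow(g$atoms), 1L)
  expect_equal(g$atoms$hcount, 4L)   # valence-derived CH4
})

test_that("writing an empty molecule is an error", {
  g <- benzene()
  g$atoms <- g$atoms[0, ]; g$bonds <- g$bonds[0, ]
  expect_error(write_molfile(g), "empty")
})

test_that("implicit hydrogen counts follow standard valences", {
  ac <- fixture_mol("acetaminophen")
  expect_equal(ac$atoms$hcount,
               c(3L, 0L, 0L, 1L, 0L, 1L, 1L, 0L, 1L, 1L, 1L))
  expect_equal(mol_formula(ac), "C8H9NO2")
  expect_equal(mol_formula(fixture_mol("bisphenol_a")), "C15H16O2")
})

test_that("canonical keys are invariant under atom reordering", {
  b1 <- benzene()
  b2 <- benzene(order = c(3, 1, 5, 2, 6, 4))
  expect_identical(canonical_key(b1), canonical_key(b2))
  expect_false(canonical_key(b1) == canonical_key(phenol_graph()))
})

test_that("hydroxylation at symmetry-equivalent BPA sites gives one canonical key", {
  bpa <- fixture_mol("bisphenol_a")
  p1 <- edit_hydroxylation(bpa, 1L)$product
  p5 <- edit_hydroxylation(bpa, 5L)$product
  expect_isomorphic(p1, p5)
  expect_identical(canonical_key(p1), canonical_key(p5))
})

test_that("canonical key equality coincides with VF2 isomorphism", {
  set.seed(421)
  mols <- c(lapply(5:10, function(n) random_molecule(n)),
            list(benzene(), phenol_graph(), cyclohexane(),
                 fixture_mol("acetaminophen")))
  # every molecule against a shuffled copy of itself and against the others
  for (g in mols) {
    n <- nrow(g$atoms)
    perm <- sample(n)
    remap <- match(seq_len(n), perm)
    b <- g$bonds; b$i <- remap[b$i]; b$j <- remap[b$j]
    shuf <- molgraph(g$atoms$element[perm], b[, c("i", "j", "order")],
                     hcount = g$atoms$hcount[perm])
    shuf <- perceive_aromaticity(shuf)
    expect_identical(canonical_key(g), canonical_key(shuf))
    expect_true(graph_isomorphic(g, shuf))
  }
  keys <- vapply(mols, canonical_key, character(1))
  for (a in seq_along(mols)) for (b in seq_along(mols)) {
    expect_equal(keys[a] == keys[b], graph_isomorphic(mols[[a]], mols[[b]]),
                 info = paste("molecules", a, b))
  }
})

test_that("SMILES input produces the same graph model as molfiles", {
  skip_if_not_installed("ChemmineR")
  skip_if_not_installed("ChemmineOB")
  bpa <- read_smiles("CC(C)(c1ccc(O)cc1)c2ccc(O)cc2")
  expect_isomorphic(bpa, fixture_mol("bisphenol_a"))
  expect_equal(mol_formula(bpa), "C15H16O2")
})
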