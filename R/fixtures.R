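# Packaged molecules, deterministic graph-edit functions, the synthetic
# reaction-pair generator and the curated lookup tables.
#
# The edit functions implement the transformation chemistry named in the
# case studies (aromatic hydroxylation, arene epoxidation, O/N-dealkylation,
# phenol -> cyclohexadienone oxidation, glucuronidation, sulfation,
# O-methylation, N-acetylation, epoxide glutathione conjugation) as direct
# Kekule-aware graph edits.  They serve two roles: constructing curated
# exemplar reactions for the packaged tables, and generating synthetic
# reaction pairs with known ground-truth edits so that the mining ->
# matching -> application pipeline can be tested round-trip without any
# external database.

#' Load a packaged fixture molecule
#'
#' @param name one of `"antipyrine"`, `"hydroxymethylantipyrine"`,
#'   `"acetaminophen"`, `"napqi"`, `"acetaminophen_glucuronide"`,
#'   `"acetaminophen_sulfate"`, `"bisphenol_a"`, `"pcb3"`.
#' @return a `molgraph`.
#' @export
fixture_mol <- function(name) {
  path <- system.file("extdata", "mol", paste0(name, ".mol"),
                      package = "proximal")
  if (!nzchar(path)) stop("no packaged molecule named ", sQuote(name))
  read_molfile(path)
}

.fragments_env <- new.env(parent = emptyenv())

#' Load the packaged conjugate fragment library
#'
#' @return named list of fragments, each with `atoms`, `bonds`, `attach`.
#' @export
load_fragments <- function() {
  if (!is.null(.fragments_env$frags)) return(.fragments_env$frags)
  raw <- yaml::read_yaml(system.file("extdata", "fragments.yaml",
                                     package = "proximal"))$fragments
  frags <- lapply(raw, function(f) {
    atoms <- data.frame(
      element = vapply(f$atoms, `[[`, character(1), "element"),
      hcount = vapply(f$atoms, `[[`, integer(1), "h"),
      stringsAsFactors = FALSE)
    bonds <- if (is.null(f$bonds))
      data.frame(i = integer(0), j = integer(0), order = integer(0))
    else data.frame(i = vapply(f$bonds, `[[`, integer(1), "i"),
                    j = vapply(f$bonds, `[[`, integer(1), "j"),
                    order = vapply(f$bonds, `[[`, integer(1), "order"))
    list(atoms = atoms, bonds = bonds, attach = f$attach)
  })
  .fragments_env$frags <- frags
  frags
}

# Graft a named fragment onto atom `at` of g with a single bond; the site
# atom loses `h_loss` implicit hydrogens.
.graft_fragment <- function(g, at, fragment, h_loss = 1L) {
  fr <- load_fragments()[[fragment]]
  if (is.null(fr)) stop("unknown fragment ", fragment)
  if (g$atoms$hcount[at] < h_loss) stop("site has no hydrogen to substitute")
  n0 <- nrow(g$atoms)
  add_bonds <- data.frame(i = n0 + fr$bonds$i, j = n0 + fr$bonds$j,
                          order = fr$bonds$order)
  add_bonds <- rbind(add_bonds,
                     data.frame(i = at, j = n0 + fr$attach, order = 1L))
  ed <- .edit_graph(g, add_atoms = fr$atoms, add_bonds = add_bonds,
                    set_h = stats::setNames(list(g$atoms$hcount[at] - h_loss),
                                            at))
  perceive_aromaticity(ed$graph)
}

# ---------------------------------------------------------------------------
# Edit functions.  Each returns list(product, center) or NULL when the edit
# does not apply at the requested site.

#' Deterministic biotransformation graph edits
#'
#' `edit_hydroxylation()` replaces an aromatic C-H by C-OH;
#' `edit_epoxidation()` bridges an aromatic double bond at `center` with an
#' oxygen (arene oxide); `edit_dealkylation()` removes a methyl from an O/N
#' heteroatom; `edit_hydroxyl_to_carbonyl()` oxidizes a phenol to the
#' cyclohexadienone (the ring hydrogen migrates to the para position);
#' `edit_glucuronidation()`, `edit_sulfation()`, `edit_methylation()` and
#' `edit_acetylation()` substitute an O-H/N-H hydrogen by the respective
#' conjugate fragment; `edit_glutathione()` opens an epoxide, leaving a
#' hydroxyl on one carbon and S-glutathionyl on the other.
#'
#' @param g a `molgraph`.
#' @param center the edited atom (see individual descriptions).
#' @return `list(product, center)` or `NULL` when the edit does not apply.
#' @name edits
NULL

#' @rdname edits
#' @export
edit_hydroxylation <- function(g, center) {
  g <- perceive_aromaticity(g)
  types <- assign_types(g)
  if (types[center] != "C8x") return(NULL)
  g2 <- .graft_fragment(g, center, "hydroxyl", h_loss = 1L)
  list(product = g2, center = center)
}

#' @rdname edits
#' @export
edit_epoxidation <- function(g, center) {
  g <- perceive_aromaticity(g)
  rows <- which((g$bonds$i == center | g$bonds$j == center) &
                  g$bonds$aromatic & g$bonds$order == 2L)
  if (!length(rows)) return(NULL)
  k <- rows[1]
  other <- if (g$bonds$i[k] == center) g$bonds$j[k] else g$bonds$i[k]
  n0 <- nrow(g$atoms)
  ed <- .edit_graph(g,
                    set_bonds = data.frame(i = center, j = other, order = 1L,
                                           aromatic = FALSE),
                    add_atoms = data.frame(element = "O", hcount = 0L),
                    add_bonds = data.frame(i = c(center, other),
                                           j = c(n0 + 1L, n0 + 1L), order = 1L))
  list(product = perceive_aromaticity(ed$graph), center = center)
}

#' @rdname edits
#' @export
edit_dealkylation <- function(g, center) {
  g <- perceive_aromaticity(g)
  if (!(g$atoms$element[center] %in% c("N", "O"))) return(NULL)
  adj <- .adjacency(g)
  methyls <- Filter(function(a) g$atoms$element[a] == "C" &&
                      g$atoms$hcount[a] == 3L && length(adj[[a]]) == 1L,
                    adj[[center]])
  if (!length(methyls)) return(NULL)
  ed <- .edit_graph(g, delete_atoms = methyls[[1]],
                    set_h = stats::setNames(list(g$atoms$hcount[center] + 1L),
                                            center))
  list(product = perceive_aromaticity(ed$graph), center = center)
}

#' @rdname edits
#' @export
edit_hydroxyl_to_carbonyl <- function(g, center) {
  g <- perceive_aromaticity(g)
  types <- assign_types(g)
  if (types[center] != "O1a") return(NULL)
  adj <- .adjacency(g)
  ipso <- adj[[center]][1]
  if (types[ipso] != "C8y") return(NULL)
  rings <- Filter(function(r) length(r) == 6L && ipso %in% r, .find_rings(g))
  if (!length(rings)) return(NULL)
  ring <- rings[[1]]
  pos <- match(ipso, ring)
  ring <- c(ring[pos:length(ring)], ring[seq_len(pos - 1L)])  # start at ipso
  para <- ring[4]
  # cyclohexa-2,5-dien-1-one bond pattern around the ring
  orders <- c(1L, 2L, 1L, 1L, 2L, 1L)
  set_bonds <- data.frame(i = ring, j = c(ring[-1], ring[1]), order = orders,
                          aromatic = FALSE)
  set_bonds <- rbind(set_bonds, data.frame(i = center, j = ipso, order = 2L,
                                           aromatic = FALSE))
  ed <- .edit_graph(g, set_bonds = set_bonds,
                    set_h = stats::setNames(
                      list(0L, g$atoms$hcount[para] + 1L),
                      c(center, para)))
  g2 <- perceive_aromaticity(ed$graph)
  if (!isTRUE(.check_valences(g2))) return(NULL)
  list(product = g2, center = center)
}

#' @rdname edits
#' @export
edit_glucuronidation <- function(g, center) {
  g <- perceive_aromaticity(g)
  if (g$atoms$element[center] != "O" || g$atoms$hcount[center] < 1L) return(NULL)
  list(product = .graft_fragment(g, center, "glucuronosyl"), center = center)
}

#' @rdname edits
#' @export
edit_sulfation <- function(g, center) {
  g <- perceive_aromaticity(g)
  if (g$atoms$element[center] != "O" || g$atoms$hcount[center] < 1L) return(NULL)
  list(product = .graft_fragment(g, center, "sulfo"), center = center)
}

#' @rdname edits
#' @export
edit_methylation <- function(g, center) {
  g <- perceive_aromaticity(g)
  if (g$atoms$element[center] != "O" || g$atoms$hcount[center] < 1L) return(NULL)
  list(product = .graft_fragment(g, center, "methyl"), center = center)
}

#' @rdname edits
#' @export
edit_acetylation <- function(g, center) {
  g <- perceive_aromaticity(g)
  if (g$atoms$element[center] != "N" || g$atoms$hcount[center] < 1L) return(NULL)
  list(product = .graft_fragment(g, center, "acetyl"), center = center)
}

#' @rdname edits
#' @export
edit_glutathione <- function(g, center) {
  g <- perceive_aromaticity(g)
  if (g$atoms$element[center] != "O") return(NULL)
  adj <- .adjacency(g)
  nb <- adj[[center]]
  if (length(nb) != 2L || !all(g$atoms$element[nb] == "C")) return(NULL)
  if (is.null(.bond_lookup(g)[[.bond_key(nb[1], nb[2])]])) return(NULL)  # need 3-ring
  ca <- min(nb)  # receives the glutathionyl sulfur
  g2 <- .graft_fragment(g, ca, "glutathionyl", h_loss = 0L)
  ed <- .edit_graph(g2, set_bonds = data.frame(i = ca, j = center, order = 0L,
                                               aromatic = FALSE),
                    set_h = stats::setNames(list(1L), center))
  g3 <- perceive_aromaticity(ed$graph)
  if (!isTRUE(.check_valences(g3))) return(NULL)
  list(product = g3, center = center)
}

.EDIT_FUNS <- list(
  hydroxylation = list(fun = "edit_hydroxylation", phase = "I"),
  epoxidation = list(fun = "edit_epoxidation", phase = "I"),
  dealkylation = list(fun = "edit_dealkylation", phase = "I"),
  hydroxyl_to_carbonyl = list(fun = "edit_hydroxyl_to_carbonyl", phase = "I"),
  glucuronidation = list(fun = "edit_glucuronidation", phase = "II",
                         enzyme = "UGT"),
  sulfation = list(fun = "edit_sulfation", phase = "II", enzyme = "SULT"),
  methylation = list(fun = "edit_methylation", phase = "II", enzyme = "COMT"),
  acetylation = list(fun = "edit_acetylation", phase = "II", enzyme = "NAT"),
  glutathione = list(fun = "edit_glutathione", phase = "II", enzyme = "GST")
)

.CYPS <- c("1A2", "2A6", "2B6", "2C8", "2C9", "2C19", "2D6", "2E1", "3A4")

# ---------------------------------------------------------------------------
# Scaffolds

# benzene with substituents: named vector position (1..6) -> code among
# CH3, OH, NH2, NHCH3, N(CH3)2, OCH3, Cl
.benzene_scaffold <- function(subs = NULL, name = "scaffold") {
  elements <- rep("C", 6)
  bonds <- data.frame(i = 1:6, j = c(2:6, 1), order = c(2L, 1L, 2L, 1L, 2L, 1L))
  add <- function(el, at) {
    elements <<- c(elements, el)
    bonds <<- rbind(bonds, data.frame(i = at, j = length(elements), order = 1L))
    length(elements)
  }
  if (!is.null(subs)) for (pos in names(subs)) {
    p <- as.integer(pos)
    switch(subs[[pos]],
      CH3 = add("C", p), OH = add("O", p), NH2 = add("N", p), Cl = add("Cl", p),
      NHCH3 = { n <- add("N", p); add("C", n) },
      `N(CH3)2` = { n <- add("N", p); add("C", n); add("C", n) },
      OCH3 = { o <- add("O", p); add("C", o) },
      stop("unknown substituent ", subs[[pos]]))
  }
  perceive_aromaticity(molgraph(elements, bonds, name = name))
}

.arene_oxide_scaffold <- function(subs = NULL, name = "arene oxide") {
  elements <- c(rep("C", 6), "O")
  bonds <- data.frame(i = c(1, 2, 3, 4, 5, 6, 1, 2),
                      j = c(2, 3, 4, 5, 6, 1, 7, 7),
                      order = c(1L, 1L, 2L, 1L, 2L, 1L, 1L, 1L))
  if (!is.null(subs)) for (pos in names(subs)) {
    p <- as.integer(pos)
    if (subs[[pos]] == "CH3") {
      elements <- c(elements, "C")
      bonds <- rbind(bonds, data.frame(i = p, j = length(elements), order = 1L))
    }
  }
  perceive_aromaticity(molgraph(elements, bonds, name = name))
}

# applicable (kind, center) pairs for a scaffold
.applicable_edits <- function(g) {
  g <- perceive_aromaticity(g)
  types <- assign_types(g)
  adj <- .adjacency(g)
  out <- list()
  addk <- function(kind, centers) {
    for (ct in centers) out[[length(out) + 1L]] <<- list(kind = kind, center = ct)
  }
  addk("hydroxylation", which(types == "C8x"))
  epox <- unique(c(g$bonds$i[g$bonds$aromatic & g$bonds$order == 2L],
                   g$bonds$j[g$bonds$aromatic & g$bonds$order == 2L]))
  addk("epoxidation", sort(epox))
  deal <- which(vapply(seq_len(nrow(g$atoms)), function(a) {
    g$atoms$element[a] %in% c("N", "O") &&
      any(vapply(adj[[a]], function(b) g$atoms$element[b] == "C" &&
                   g$atoms$hcount[b] == 3L && length(adj[[b]]) == 1L, logical(1)))
  }, logical(1)))
  addk("dealkylation", deal)
  phen <- which(types == "O1a" &
                  vapply(seq_len(nrow(g$atoms)), function(a)
                    length(adj[[a]]) == 1L && types[adj[[a]][1]] == "C8y",
                    logical(1)))
  addk("hydroxyl_to_carbonyl", phen)
  ohs <- which(g$atoms$element == "O" & g$atoms$hcount >= 1L)
  addk("glucuronidation", ohs); addk("sulfation", ohs); addk("methylation", ohs)
  addk("acetylation", which(g$atoms$element == "N" & g$atoms$hcount >= 1L))
  epo <- which(vapply(seq_len(nrow(g$atoms)), function(a) {
    g$atoms$element[a] == "O" && length(adj[[a]]) == 2L &&
      all(g$atoms$element[adj[[a]]] == "C") &&
      !is.null(.bond_lookup(g)[[.bond_key(adj[[a]][1], adj[[a]][2])]])
  }, logical(1)))
  addk("glutathione", epo)
  out
}

#' Generate synthetic reaction pairs with known edits
#'
#' Samples small aromatic scaffolds (substituted benzenes, anilines,
#' phenols, N-methyl amines, occasional arene oxides), applies one randomly
#' chosen applicable edit per scaffold and emits reactant-product records
#' with the ground-truth edit attached (attributes `kind` and `center` on
#' each record).  Deterministic for a fixed seed; scaffolds with no
#' applicable edit are resampled.
#'
#' @param seed integer seed.
#' @param n number of records.
#' @return list of `reaction_record` objects.
#' @export
generate_synthetic_reactions <- function(seed, n) {
  stopifnot(n >= 0L)
  if (n == 0L) return(list())
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  subs_pool <- c("CH3", "OH", "NH2", "NHCH3", "N(CH3)2", "OCH3", "Cl")
  out <- vector("list", n)
  i <- 1L
  while (i <= n) {
    if (stats::runif(1) < 0.2) {
      nsub <- sample(0:1, 1)
      subs <- if (nsub) stats::setNames(list("CH3"), sample(3:6, 1)) else NULL
      g <- .arene_oxide_scaffold(subs, name = sprintf("scaffold%04d", i))
    } else {
      nsub <- sample(0:3, 1)
      subs <- NULL
      if (nsub) {
        pos <- sample(1:6, nsub)
        subs <- stats::setNames(as.list(sample(subs_pool, nsub, replace = TRUE)),
                                pos)
      }
      g <- .benzene_scaffold(subs, name = sprintf("scaffold%04d", i))
    }
    edits <- .applicable_edits(g)
    if (!length(edits)) next
    kinds <- unique(vapply(edits, `[[`, character(1), "kind"))
    kind <- sample(kinds, 1)
    cand <- Filter(function(e) e$kind == kind, edits)
    pick <- cand[[sample(length(cand), 1)]]
    res <- do.call(.EDIT_FUNS[[kind]]$fun, list(g, pick$center))
    if (is.null(res)) next
    phase <- .EDIT_FUNS[[kind]]$phase
    enzyme <- if (phase == "I") sample(.CYPS, 1) else .EDIT_FUNS[[kind]]$enzyme
    rec <- reaction_record(sprintf("syn%04d", i), enzyme, phase,
                           g, res$product, source = "synthetic")
    attr(rec, "kind") <- kind
    attr(rec, "center") <- res$center
    out[[i]] <- rec
    i <- i + 1L
  }
  out
}

# ---------------------------------------------------------------------------
# Curated tables

.curated_env <- new.env(parent = emptyenv())

#' Curated lookup tables for the packaged case studies
#'
#' Exemplar reactions are constructed with the deterministic edit functions
#' (plus the packaged acetaminophen / N-acetyl-p-benzoquinone-imine and
#' antipyrine pairs) and mined into Phase I / Phase II tables.  Enzyme
#' annotations for the bisphenol A and 4-chlorobiphenyl rules carry the CYP
#' sets of the published score tables; conjugation rules carry the EC
#' numbers of the respective transferases.
#'
#' @return list with `phase1`, `phase2` lookup tables and `records`.
#' @export
curated_tables <- function() {
  if (!is.null(.curated_env$tabs)) return(.curated_env$tabs)
  bpa <- fixture_mol("bisphenol_a"); pcb <- fixture_mol("pcb3")
  phenol <- .benzene_scaffold(list(`1` = "OH"), "phenol")
  catechol <- .benzene_scaffold(list(`1` = "OH", `2` = "OH"), "catechol")
  aniline <- .benzene_scaffold(list(`1` = "NH2"), "aniline")
  nmethylaniline <- .benzene_scaffold(list(`1` = "NHCH3"), "N-methylaniline")
  bpa_oh <- edit_hydroxylation(bpa, 1L)$product; bpa_oh$name <- "5-hydroxy BPA"
  pcb_epox_meta <- edit_epoxidation(pcb, 10L)$product
  rec <- function(id, enz, phase, r, res)
    reaction_record(id, enz, phase, r, res$product, source = "fixture")
  records <- list(
    rec("bpa_hydroxylation", c("1A1", "1A2", "1B1", "3A4"), "I",
        bpa, edit_hydroxylation(bpa, 1L)),
    rec("bpa_carbonyl", c("1A2", "2D6", "2E1"), "I",
        bpa, edit_hydroxyl_to_carbonyl(bpa, 7L)),
    rec("bpa_epoxide", "2E1", "I", bpa, edit_epoxidation(bpa, 1L)),
    reaction_record("acetaminophen_napqi", c("1A2", "2E1", "3A4"), "I",
                    fixture_mol("acetaminophen"), fixture_mol("napqi")),
    reaction_record("antipyrine_hydroxymethyl", c("1A2", "2C9", "3A4"), "I",
                    fixture_mol("antipyrine"),
                    fixture_mol("hydroxymethylantipyrine")),
    rec("pcb3_para_hydroxylation",
        c("1B1", "2B6", "2C8", "2C9", "2C18", "2C19", "2D6", "2E1", "3A4", "3A5"),
        "I", pcb, edit_hydroxylation(pcb, 11L)),
    rec("pcb3_meta_hydroxylation", c("2B6", "3A4"), "I",
        pcb, edit_hydroxylation(pcb, 10L)),
    rec("pcb3_ortho_hydroxylation", "2D6", "I", pcb, edit_hydroxylation(pcb, 9L)),
    rec("pcb3_ringa_hydroxylation", "2E1", "I", pcb, edit_hydroxylation(pcb, 3L)),
    rec("pcb3_meta_epoxide",
        c("1A1", "1B1", "1A2", "2A6", "2B6", "2C9", "2C19", "2E1", "3A4"),
        "I", pcb, edit_epoxidation(pcb, 10L)),
    rec("pcb3_para_epoxide", "2E1", "I", pcb, edit_epoxidation(pcb, 11L)),
    rec("pcb3_ortho_epoxide", c("1A1", "1B1", "2C8", "2C9", "2E1", "3A4"),
        "I", pcb, edit_epoxidation(pcb, 9L)),
    rec("n_demethylation", c("2D6", "3A4"), "I",
        nmethylaniline, edit_dealkylation(nmethylaniline, 7L)),
    rec("phenol_glucuronide", "UGT", "II", phenol,
        edit_glucuronidation(phenol, 7L)),
    rec("phenol_sulfate", "SULT", "II", phenol, edit_sulfation(phenol, 7L)),
    rec("hydroxybpa_glucuronide", "UGT", "II", bpa_oh,
        edit_glucuronidation(bpa_oh, 18L)),
    rec("hydroxybpa_sulfate", "SULT", "II", bpa_oh, edit_sulfation(bpa_oh, 18L)),
    rec("catechol_methylation", "COMT", "II", catechol,
        edit_methylation(catechol, 7L)),
    rec("epoxide_glutathione", "GST", "II", pcb_epox_meta,
        edit_glutathione(pcb_epox_meta, 14L)),
    rec("aniline_acetylation", "NAT", "II", aniline,
        edit_acetylation(aniline, 7L))
  )
  tabs <- build_tables(records)
  tabs$records <- records
  .curated_env$tabs <- tabs
  tabs
}

#' Restrict lookup tables to rules from given exemplar records
#'
#' @param tables list with `phase1`, `phase2`.
#' @param ids provenance record ids to keep.
#' @return filtered tables.
#' @export
filter_rules <- function(tables, ids) {
  filt <- function(tab) {
    out <- .new_table(tab$phase)
    for (e in tab$entries) {
      for (rule in e$rules) {
        prov <- strsplit(rule$provenance, ";")[[1]]
        if (any(prov %in% ids)) out <- .table_add(out, e$key, rule)
      }
    }
    out
  }
  list(phase1 = filt(tables$phase1), phase2 = filt(tables$phase2))
}

# ---------------------------------------------------------------------------
# Demo

#' Run the bisphenol A and 4-chlorobiphenyl case studies
#'
#' Predicts Phase I and Phase II products for both chemicals with the
#' curated tables, scores and ranks the Phase I products from the packaged
#' CYP activity/abundance averages, and prints the result tables.
#'
#' @param quiet suppress printing.
#' @return invisibly, a list with per-chemical `products` (list of
#'   `predicted_product`) and `ranking` (data frame).
#' @export
proximal_demo <- function(quiet = FALSE) {
  tabs <- curated_tables()
  stats <- load_enzyme_stats()
  out <- list()
  for (case in c("bisphenol_a", "pcb3")) {
    g <- fixture_mol(case)
    products <- predict_metabolites(g, tabs, phases = c("I", "II"), depth = 2L)
    smry <- products_summary(products)
    is_p1 <- smry$phase_chain == "I"
    ranking <- NULL
    if (any(is_p1)) {
      ranking <- rank_predictions(
        data.frame(id = smry$id[is_p1], enzymes = smry$enzymes[is_p1],
                   stringsAsFactors = FALSE), stats)
    }
    if (!quiet) {
      cat("==", g$name, "==\n")
      cat(sprintf("%d predicted products (%d Phase I, %d via conjugation)\n",
                  nrow(smry), sum(is_p1), sum(!is_p1)))
      print(smry, row.names = FALSE)
      if (!is.null(ranking)) {
        cat("\nPhase I ranking (score = sum over CYPs of activity x abundance):\n")
        print(ranking, row.names = FALSE)
      }
      cat("\n")
    }
    out[[case]] <- list(products = products, summary = smry, ranking = ranking)
  }
  invisible(out)
}
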