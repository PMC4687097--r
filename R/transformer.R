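# Candidate-site enumeration, lookup-table matching and metabolite
# generation for a query molecule.
#
# Every heavy atom of the query is a candidate reaction center; sites
# sharing an identical (center type, adjacent multiset, distant multiset)
# key form one symmetry class and only the lowest-index representative is
# transformed, so products generated at equivalent sites collapse to one
# output.  Matching against the lookup tables is exact on all three key
# fields.  A matching rule is applied by embedding its stored pattern into
# the query around the site (type-exact inside the two-level substructure,
# element-level beyond it) and replaying the recorded edits; Kekule orders
# of aromatic bonds the rule does not set explicitly are re-derived from
# valence constraints, so application is independent of the query's Kekule
# rendering.  Products that would violate valence are rejected
# individually, never the run.

#' Enumerate candidate reaction-center sites
#'
#' @param g a `molgraph`.
#' @param types optional precomputed KEGG types.
#' @return data frame with one row per heavy atom: `atom`, `key_string`,
#'   `symmetry_class` (integer id shared by equal-key sites) and
#'   `representative` (TRUE for the lowest-index member of each class).
#'   The `lookup_key` objects are attached as attribute `"keys"`.
#' @export
enumerate_sites <- function(g, types = NULL) {
  g <- perceive_aromaticity(g)
  if (is.null(types)) types <- assign_types(g)
  keys <- lapply(seq_len(nrow(g$atoms)), function(a) extract_key(g, types, a))
  ks <- vapply(keys, key_string, character(1))
  cls <- as.integer(factor(ks, levels = unique(ks)))
  rep_ <- !duplicated(cls)
  out <- data.frame(atom = seq_len(nrow(g$atoms)), key_string = ks,
                    symmetry_class = cls, representative = rep_,
                    stringsAsFactors = FALSE)
  attr(out, "keys") <- keys
  out
}

#' Match unique sites against a lookup table
#'
#' Exact equality on all three key fields; one output row per matching
#' rule per symmetry-class representative.  Sites whose key contains a
#' fallback atom type never match.
#'
#' @param sites data frame from [enumerate_sites()].
#' @param table a `lookup_table`.
#' @return list of matches: each `list(atom, key_string, rule)`.
#' @export
match_sites <- function(sites, table) {
  out <- list()
  for (rix in which(sites$representative)) {
    ks <- sites$key_string[rix]
    if (grepl("?", ks, fixed = TRUE)) next
    entry <- table$entries[[ks]]
    if (is.null(entry)) next
    for (rule in entry$rules) {
      out[[length(out) + 1L]] <- list(atom = sites$atom[rix],
                                      key_string = ks, rule = rule)
    }
  }
  out
}

# ---------------------------------------------------------------------------
# Rule application

# Embed the rule pattern into g anchored at `site`; returns the image
# vector (query atom per pattern atom) or NULL.  Substructure atoms
# (center/adjacent/distant roles) must match KEGG types; extended-pattern
# atoms match elements only.  Pattern bonds must exist in the query with
# the same aromatic flag, and for non-aromatic bonds the same Kekule
# order.  Deterministic: candidates tried in ascending index order; all
# embeddings are generated lazily until one yields a valid product.
.embed_pattern <- function(g, types, rule, site, max_embeddings = 200L) {
  pat <- rule$pattern
  npat <- nrow(pat$atoms)
  adjg <- .adjacency(g)
  lk <- .bond_lookup(g)
  # pattern adjacency over reactant-present bonds
  padj <- vector("list", npat)
  for (k in seq_len(nrow(pat$bonds))) {
    if (is.na(pat$bonds$order_r[k])) next
    i <- pat$bonds$li[k]; j <- pat$bonds$lj[k]
    padj[[i]] <- c(padj[[i]], list(c(j, k))); padj[[j]] <- c(padj[[j]], list(c(i, k)))
  }
  # BFS order from the center (local index 1)
  ordv <- 1L; seen <- logical(npat); seen[1] <- TRUE
  qq <- 1L
  while (length(qq)) {
    v <- qq[1]; qq <- qq[-1]
    for (e in padj[[v]]) if (!seen[e[1]]) { seen[e[1]] <- TRUE
      ordv <- c(ordv, e[1]); qq <- c(qq, e[1]) }
  }
  if (length(ordv) < npat) ordv <- c(ordv, setdiff(seq_len(npat), ordv))
  results <- list(); count <- 0L
  img <- integer(npat)
  assign_next <- function(pos) {
    if (count >= max_embeddings) return()
    if (pos > npat) { count <<- count + 1L
      results[[count]] <<- img; return() }
    u <- ordv[pos]
    placed <- ordv[seq_len(pos - 1L)]
    # candidates: adjacent in g to the image of a placed pattern neighbor
    anchors <- Filter(function(e) e[1] %in% placed, padj[[u]])
    cands <- if (u == 1L) site else if (length(anchors))
      sort(unique(unlist(lapply(anchors, function(e) adjg[[img[e[1]]]]))))
    else seq_len(nrow(g$atoms))
    for (cand in cands) {
      if (cand %in% img[placed]) next
      if (g$atoms$element[cand] != pat$atoms$element[u]) next
      if (pat$atoms$role[u] %in% c("center", "adjacent", "distant") &&
          types[cand] != pat$atoms$type[u]) next
      ok <- TRUE
      for (e in padj[[u]]) {
        v <- e[1]
        if (!(v %in% placed)) next
        row <- lk[[.bond_key(cand, img[v])]]
        if (is.null(row)) { ok <- FALSE; break }
        bk <- pat$bonds[e[2], ]
        if (g$bonds$aromatic[row] != bk$arom_r) { ok <- FALSE; break }
        if (!bk$arom_r && g$bonds$order[row] != bk$order_r) { ok <- FALSE; break }
      }
      if (!ok) next
      img[u] <<- cand
      assign_next(pos + 1L)
      img[u] <<- 0L
      if (count >= max_embeddings) return()
    }
  }
  assign_next(1L)
  results
}

#' Apply a transformation rule at a site
#'
#' Replays the rule's edits on the query: removed atoms are deleted, the
#' added fragment is grafted at its recorded attachment positions,
#' bond-order/aromaticity changes are applied, per-atom hydrogen-count
#' deltas are replayed, untouched aromatic Kekule orders are re-solved
#' from valence constraints, and the product is re-perceived and re-typed.
#' Grafts that would violate valence reject the product (returns `NULL`
#' with a diagnostic attribute accessible via `attr(,"reason")` on the
#' `NULL`-replacement sentinel).
#'
#' @param g query `molgraph`.
#' @param site query atom index (a symmetry-class representative).
#' @param rule a `transformation_rule` whose key equals the site's key.
#' @param types optional precomputed KEGG types of `g`.
#' @return a `predicted_product` (list with `graph`, `site`, `rule`,
#'   `enzymes`, `new_atoms`, `center_image`, `canonical`) or `NULL` when
#'   no embedding yields a valid product.
#' @export
apply_rule <- function(g, site, rule, types = NULL) {
  g <- perceive_aromaticity(g)
  if (is.null(types)) types <- assign_types(g)
  pat <- rule$pattern
  embeddings <- .embed_pattern(g, types, rule, site)
  for (img in embeddings) {
    res <- .replay_rule(g, rule, img)
    if (!is.null(res)) {
      res$site <- site
      res$rule <- rule
      res$enzymes <- rule$enzymes
      res$canonical <- canonical_key(res$graph)
      class(res) <- "predicted_product"
      return(res)
    }
  }
  NULL
}

.replay_rule <- function(g, rule, img) {
  pat <- rule$pattern
  removed_q <- img[which(pat$atoms$removed)]
  # removed atoms may not carry query bonds the pattern does not cover
  if (length(removed_q)) {
    adjg <- .adjacency(g)
    for (rq in removed_q) {
      if (length(setdiff(adjg[[rq]], img))) return(NULL)
    }
  }
  set_bonds <- NULL
  for (k in seq_len(nrow(pat$bonds))) {
    bk <- pat$bonds[k, ]
    qi <- img[bk$li]; qj <- img[bk$lj]
    if (is.na(bk$order_r)) {                       # bond formed
      sb <- data.frame(i = qi, j = qj, order = bk$order_p, aromatic = bk$arom_p)
    } else if (!bk$present_p) {                    # bond broken (not via removal)
      if (any(c(qi, qj) %in% removed_q)) next
      sb <- data.frame(i = qi, j = qj, order = 0L, aromatic = FALSE)
    } else if (bk$order_p != bk$order_r || bk$arom_p != bk$arom_r) {
      sb <- data.frame(i = qi, j = qj, order = bk$order_p, aromatic = bk$arom_p)
    } else next
    set_bonds <- rbind(set_bonds, sb)
  }
  nfrag <- nrow(rule$fragment$atoms)
  add_atoms <- if (nfrag) rule$fragment$atoms else NULL
  add_bonds <- NULL
  nold <- nrow(g$atoms)
  if (nfrag) {
    fb <- rule$fragment$bonds
    if (nrow(fb))
      add_bonds <- data.frame(i = nold + fb$fi, j = nold + fb$fj,
                              order = fb$order, aromatic = fb$aromatic)
    fa <- rule$fragment$attach
    if (nrow(fa))
      add_bonds <- rbind(add_bonds,
                         data.frame(i = nold + fa$fatom, j = img[fa$patom],
                                    order = fa$order, aromatic = fa$aromatic))
  }
  # hydrogen-count deltas on surviving pattern atoms
  set_h <- list()
  for (u in seq_len(nrow(pat$atoms))) {
    if (pat$atoms$removed[u]) next
    d <- pat$atoms$h_p[u] - pat$atoms$h_r[u]
    if (is.na(d) || d == 0L) next
    newh <- g$atoms$hcount[img[u]] + d
    if (newh < 0L) return(NULL)
    set_h[[as.character(img[u])]] <- newh
  }
  # track which (old-index) bond pairs were explicitly set
  explicit <- character(0)
  if (!is.null(set_bonds)) explicit <- .bond_key(set_bonds$i, set_bonds$j)
  ed <- tryCatch(.edit_graph(g, delete_atoms = removed_q, set_bonds = set_bonds,
                             add_atoms = add_atoms, add_bonds = add_bonds,
                             set_h = set_h),
                 error = function(e) NULL)
  if (is.null(ed)) return(NULL)
  g2 <- ed$graph
  # free bonds: aromatic in the query, not explicitly set, both ends surviving
  was_arom <- g$bonds[g$bonds$aromatic, , drop = FALSE]
  free_rows <- integer(0)
  if (nrow(was_arom)) {
    for (k in seq_len(nrow(was_arom))) {
      oi <- was_arom$i[k]; oj <- was_arom$j[k]
      if (.bond_key(oi, oj) %in% explicit) next
      ni <- ed$map[oi]; nj <- ed$map[oj]
      if (is.na(ni) || is.na(nj)) next
      row <- .bond_lookup(g2)[[.bond_key(ni, nj)]]
      if (!is.null(row)) free_rows <- c(free_rows, row)
    }
  }
  solved <- .solve_kekule(g2, free_rows)
  if (is.null(solved)) return(NULL)
  g2$bonds$order <- solved
  g2 <- perceive_aromaticity(g2)
  if (!isTRUE(.check_valences(g2))) return(NULL)
  list(graph = g2, center_image = ed$map[img[1]],
       new_atoms = ed$new_atoms)
}

#' @export
print.predicted_product <- function(x, ...) {
  cat(sprintf("<predicted_product> %s at atom %d (phase %s%s; enzymes %s)\n",
              mol_formula(x$graph), x$site,
              paste(x$phase_chain %||% x$rule$phase, collapse = ">"),
              "", paste(x$enzymes, collapse = ",")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# Prediction driver

#' Predict biotransformation products of a query molecule
#'
#' Phase I rules are applied to the query, Phase II rules to the query and
#' (at `depth >= 2`) to each Phase I product.  When chaining onto a Phase I
#' product, candidate sites are restricted to the atoms that step
#' introduced (added fragment atoms and the reaction-center image): the
#' atoms introduced by functionalization are the centers available for
#' conjugation.  Products are deduplicated by canonical key with enzyme
#' sets merged across generation paths, and returned in a stable order
#' (phase chain, then site atom index, then canonical key).
#'
#' @param g query `molgraph`.
#' @param tables list with `phase1` and `phase2` lookup tables.
#' @param phases character subset of `c("I", "II")`.
#' @param depth 1 applies single transformations only; 2 (default) also
#'   conjugates Phase I products.
#' @return list of `predicted_product` objects, each with a `phase_chain`.
#' @export
predict_metabolites <- function(g, tables, phases = c("I", "II"), depth = 2L) {
  g <- perceive_aromaticity(g)
  query_key <- canonical_key(g)
  types <- assign_types(g)
  sites <- enumerate_sites(g, types)
  acc <- new.env(parent = emptyenv()); acc$out <- list()
  push <- function(prod, chain) {
    if (prod$canonical == query_key) return()
    hit <- NULL
    for (t in seq_along(acc$out))
      if (acc$out[[t]]$canonical == prod$canonical) { hit <- t; break }
    if (!is.null(hit)) {
      acc$out[[hit]]$enzymes <- sort(unique(c(acc$out[[hit]]$enzymes, prod$enzymes)))
      return()
    }
    prod$phase_chain <- chain
    acc$out[[length(acc$out) + 1L]] <- prod
  }
  phase1_products <- list()
  if ("I" %in% phases) {
    for (m in match_sites(sites, tables$phase1)) {
      prod <- apply_rule(g, m$atom, m$rule, types)
      if (!is.null(prod)) {
        push(prod, "I")
        phase1_products[[length(phase1_products) + 1L]] <- prod
      }
    }
  }
  if ("II" %in% phases) {
    for (m in match_sites(sites, tables$phase2)) {
      prod <- apply_rule(g, m$atom, m$rule, types)
      if (!is.null(prod)) push(prod, "II")
    }
    if (depth >= 2L && "I" %in% phases) {
      for (pp in phase1_products) {
        g1 <- pp$graph
        t1 <- assign_types(g1)
        s1 <- enumerate_sites(g1, t1)
        eligible <- c(pp$new_atoms, pp$center_image)
        s1$representative <- s1$representative & s1$atom %in% eligible
        # ensure one representative per class among eligible atoms
        for (cl in unique(s1$symmetry_class[s1$atom %in% eligible])) {
          members <- s1$atom[s1$symmetry_class == cl & s1$atom %in% eligible]
          s1$representative[s1$atom %in% members] <- s1$atom[s1$atom %in% members] == min(members)
        }
        for (m in match_sites(s1, tables$phase2)) {
          prod <- apply_rule(g1, m$atom, m$rule, t1)
          if (is.null(prod)) next
          prod$site <- pp$site       # report the originating query site
          prod$enzymes <- sort(unique(c(pp$enzymes, prod$enzymes)))
          push(prod, c("I", "II"))
        }
      }
    }
  }
  out <- acc$out
  if (!length(out)) return(out)
  chain_rank <- vapply(out, function(x)
    match(paste(x$phase_chain, collapse = ">"), c("I", "II", "I>II")), integer(1))
  sitev <- vapply(out, function(x) x$site, integer(1))
  canv <- vapply(out, function(x) x$canonical, character(1))
  out[order(chain_rank, sitev, canv)]
}

#' Summarize predicted products as a data frame
#'
#' @param products list from [predict_metabolites()].
#' @return data frame with `id`, `phase_chain`, `site`, `formula`,
#'   `enzymes` (comma-separated) and `rule_provenance`.
#' @export
products_summary <- function(products) {
  if (!length(products))
    return(data.frame(id = character(0), phase_chain = character(0),
                      site = integer(0), formula = character(0),
                      enzymes = character(0), rule_provenance = character(0)))
  data.frame(
    id = sprintf("P%02d", seq_along(products)),
    phase_chain = vapply(products, function(x)
      paste(x$phase_chain, collapse = ">"), character(1)),
    site = vapply(products, function(x) x$site, integer(1)),
    formula = vapply(products, function(x) mol_formula(x$graph), character(1)),
    enzymes = vapply(products, function(x)
      paste(x$enzymes, collapse = ","), character(1)),
    rule_provenance = vapply(products, function(x)
      x$rule$provenance, character(1)),
    stringsAsFactors = FALSE)
}

#' Write predicted products to a directory
#'
#' One molfile per product plus a `products.tsv` summary.
#'
#' @param products list from [predict_metabolites()].
#' @param dir output directory (created if needed).
#' @return the summary data frame, invisibly.
#' @export
write_products <- function(products, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  smry <- products_summary(products)
  for (t in seq_along(products)) {
    products[[t]]$graph$name <- smry$id[t]
    write_molfile(products[[t]]$graph, file.path(dir, paste0(smry$id[t], ".mol")))
  }
  utils::write.table(smry, file.path(dir, "products.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(smry)
}
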