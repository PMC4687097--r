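# Lookup-table construction from aligned reaction pairs.
#
# Each reaction center (an aligned reactant atom whose KEGG type differs
# from its product image) contributes one key-value entry: the key encodes
# the center's type plus the type multisets of its adjacent and distant
# neighbors; the value records everything needed to replay the
# transformation on a query molecule (product center type, added fragment
# with attachment bonds, removed atoms, bond-order and hydrogen-count
# changes).  Changes outside the two-level substructure are carried in an
# extended match pattern so the product structure can be regenerated
# exactly; additions/removals outside the substructure reject the rule.

.PHASE2_EC <- c(UGT = "2.4.1.17", SULT = "2.8.2.1", NAT = "2.3.1.5",
                GST = "2.5.1.18", TPMT = "2.1.1.67", COMT = "2.1.1.6")

#' Normalize an enzyme name
#'
#' CYP names are reduced to subfamily tokens (`"CYP3A4"` -> `"3A4"`);
#' Phase II transferase abbreviations are mapped to EC numbers.
#'
#' @param x character vector of enzyme names.
#' @return normalized character vector.
#' @export
normalize_enzyme <- function(x) {
  out <- trimws(x)
  out <- sub("^[Cc][Yy][Pp]\\s*", "", out)
  ec <- .PHASE2_EC[toupper(out)]
  unname(ifelse(is.na(ec), toupper(out), ec))
}

#' Construct a reaction record
#'
#' @param id record identifier.
#' @param enzyme enzyme name(s); normalized with [normalize_enzyme()].
#' @param phase `"I"` or `"II"`.
#' @param reactant,product `molgraph` objects.
#' @param source provenance tag (`"fixture"`, `"synthetic"`, `"imported"`).
#' @return a `reaction_record`.
#' @export
reaction_record <- function(id, enzyme, phase, reactant, product,
                            source = "fixture") {
  stopifnot(phase %in% c("I", "II"), inherits(reactant, "molgraph"),
            inherits(product, "molgraph"))
  enzyme <- normalize_enzyme(enzyme)
  if (!length(enzyme) || !all(nzchar(enzyme))) stop("enzyme must be non-empty")
  structure(list(id = id, enzyme = enzyme, phase = phase,
                 reactant = reactant, product = product, source = source),
            class = "reaction_record")
}

# ---------------------------------------------------------------------------
# Keys

#' Extract the lookup key of a reaction-center candidate
#'
#' The key has three fields: the KEGG type of the center, the type multiset
#' of its adjacent neighbors (atoms one bond away) and the type multiset of
#' its distant neighbors (atoms two bonds away, excluding the adjacent
#' atoms themselves; the center's own type is always included, since the
#' center is a neighbor of each of its neighbors).
#'
#' @param g a `molgraph`.
#' @param types KEGG types from [assign_types()].
#' @param center atom index.
#' @return a `lookup_key`: list with `rc`, `adjacent`, `distant` (sorted).
#' @export
extract_key <- function(g, types, center) {
  adj <- .adjacency(g)
  a <- adj[[center]]
  dist_atoms <- setdiff(sort(unique(unlist(adj[a]))), c(center, a))
  structure(list(rc = types[center],
                 adjacent = sort(types[a]),
                 distant = sort(c(types[center], types[dist_atoms]))),
            class = "lookup_key")
}

#' @export
print.lookup_key <- function(x, ...) {
  cat(sprintf("(%s; {%s}; {%s})\n", x$rc,
              paste(x$adjacent, collapse = ", "),
              paste(x$distant, collapse = ", ")))
  invisible(x)
}

#' @rdname extract_key
#' @param key a `lookup_key`.
#' @return `key_string()`: the canonical string form used for table lookup.
#' @export
key_string <- function(key) {
  paste(key$rc, paste(key$adjacent, collapse = ","),
        paste(key$distant, collapse = ","), sep = "|")
}

.key_has_fallback <- function(key) {
  any(.is_fallback_type(c(key$rc, key$adjacent, key$distant)))
}

# ---------------------------------------------------------------------------
# Reaction centers

#' Detect reaction centers of an aligned reactant-product pair
#'
#' A reaction center is an aligned reactant atom whose KEGG type differs
#' from the type of its product image.
#'
#' @param a an `atom_alignment`.
#' @param r_types,p_types KEGG types of the two molecules.
#' @return ascending integer vector of reactant atom indices.
#' @export
find_reaction_centers <- function(a, r_types, p_types) {
  if (!nrow(a$pairs)) return(integer(0))
  diff <- r_types[a$pairs[, 1]] != p_types[a$pairs[, 2]]
  sort(unname(a$pairs[diff, 1]))
}

# ---------------------------------------------------------------------------
# Rule extraction

#' Extract the transformation rule at one reaction center
#'
#' Builds the key from the reactant and a replayable value from the
#' reactant-product difference: the product center type, the added product
#' fragment (atoms unmatched by the alignment) with its attachment bonds,
#' removed reactant atoms (unmatched leaving groups, e.g. the methyl of an
#' N-demethylation), bond-order/aromaticity changes and per-atom hydrogen
#' changes.  Fragment attachments and removed atoms outside the center's
#' two-level substructure reject the rule (the key could not license them).
#'
#' @param rec a `reaction_record`.
#' @param center reactant atom index (must be a reaction center).
#' @param a alignment from [max_common_subgraph()]; computed when `NULL`.
#' @return list `(key, rule)` where `rule` is a `transformation_rule`.
#' @export
extract_rule <- function(rec, center, a = NULL) {
  r <- perceive_aromaticity(rec$reactant); p <- perceive_aromaticity(rec$product)
  if (is.null(a)) a <- max_common_subgraph(r, p)
  r_types <- assign_types(r); p_types <- assign_types(p)
  centers <- find_reaction_centers(a, r_types, p_types)
  if (!(center %in% centers))
    stop("atom ", center, " is not a reaction center of this pair")
  r2p <- stats::setNames(a$pairs[, 2], a$pairs[, 1])
  p2r <- stats::setNames(a$pairs[, 1], a$pairs[, 2])
  matched_r <- a$pairs[, 1]; matched_p <- a$pairs[, 2]
  adj <- .adjacency(r)
  subs <- c(center, sort(adj[[center]]),
            setdiff(sort(unique(unlist(adj[adj[[center]]]))),
                    c(center, adj[[center]])))
  key <- extract_key(r, r_types, center)
  if (.key_has_fallback(key))
    stop("key at atom ", center, " contains a fallback atom type")

  removed <- setdiff(seq_len(nrow(r$atoms)), matched_r)
  if (length(setdiff(removed, subs)))
    stop("pattern not local: removed atoms ",
         paste(setdiff(removed, subs), collapse = ","),
         " lie outside the two-level substructure")

  frag_p <- setdiff(seq_len(nrow(p$atoms)), matched_p)
  attach <- p$bonds[(p$bonds$i %in% frag_p) != (p$bonds$j %in% frag_p), , drop = FALSE]
  anchors_r <- integer(0)
  if (nrow(attach)) {
    anchor_p <- ifelse(attach$i %in% frag_p, attach$j, attach$i)
    anchors_r <- as.integer(p2r[as.character(anchor_p)])
    if (length(setdiff(anchors_r, subs)))
      stop("pattern not local: product fragment attaches outside the two-level substructure")
  }

  # changed bonds among aligned atoms (presence, Kekule order or aromatic flag)
  lk_r <- .bond_lookup(r); lk_p <- .bond_lookup(p)
  changed <- data.frame(a = integer(0), b = integer(0), order_r = integer(0),
                        arom_r = logical(0), present_p = logical(0),
                        order_p = integer(0), arom_p = logical(0))
  pairs_seen <- character(0)
  for (k in seq_len(nrow(r$bonds))) {
    i <- r$bonds$i[k]; j <- r$bonds$j[k]
    if (!(i %in% matched_r && j %in% matched_r)) next
    pk <- lk_p[[.bond_key(r2p[[as.character(i)]], r2p[[as.character(j)]])]]
    pairs_seen <- c(pairs_seen, .bond_key(i, j))
    if (is.null(pk)) {
      changed <- rbind(changed, data.frame(a = i, b = j, order_r = r$bonds$order[k],
                                           arom_r = r$bonds$aromatic[k],
                                           present_p = FALSE, order_p = NA_integer_,
                                           arom_p = FALSE))
    } else if (p$bonds$order[pk] != r$bonds$order[k] ||
               p$bonds$aromatic[pk] != r$bonds$aromatic[k]) {
      changed <- rbind(changed, data.frame(a = i, b = j, order_r = r$bonds$order[k],
                                           arom_r = r$bonds$aromatic[k],
                                           present_p = TRUE,
                                           order_p = p$bonds$order[pk],
                                           arom_p = p$bonds$aromatic[pk]))
    }
  }
  for (k in seq_len(nrow(p$bonds))) {   # bonds formed between aligned atoms
    i <- p$bonds$i[k]; j <- p$bonds$j[k]
    if (!(i %in% matched_p && j %in% matched_p)) next
    ri <- p2r[[as.character(i)]]; rj <- p2r[[as.character(j)]]
    if (.bond_key(ri, rj) %in% pairs_seen) next
    if (is.null(lk_r[[.bond_key(ri, rj)]]))
      changed <- rbind(changed, data.frame(a = ri, b = rj, order_r = NA_integer_,
                                           arom_r = FALSE, present_p = TRUE,
                                           order_p = p$bonds$order[k],
                                           arom_p = p$bonds$aromatic[k]))
  }

  hdelta_atoms <- matched_r[r$atoms$hcount[matched_r] !=
                              p$atoms$hcount[r2p[as.character(matched_r)]]]

  # extended pattern: substructure + changed-bond endpoints + H-changed +
  # shortest-path connectors back to the center; finally closed over the
  # immediate neighbors of every pattern atom ("context" atoms, matched by
  # element only) so that replay is anchored to the exemplar's actual
  # environment and cannot slide onto a mirror-equivalent site
  patoms <- unique(c(subs, changed$a, changed$b, hdelta_atoms, anchors_r, removed))
  sk <- .igraph_skeleton(r)
  for (t in setdiff(patoms, center)) {
    sp <- igraph::shortest_paths(sk, from = center, to = t)$vpath[[1]]
    patoms <- union(patoms, as.integer(sp))
  }
  context <- setdiff(sort(unique(unlist(adj[patoms]))), patoms)
  extra <- setdiff(sort(patoms), subs)
  plist <- c(subs, extra, context)
  roles <- c("center", rep("adjacent", length(adj[[center]])),
             rep("distant", length(subs) - 1L - length(adj[[center]])),
             rep("ext", length(extra)), rep("context", length(context)))
  loc <- stats::setNames(seq_along(plist), plist)
  h_p <- rep(NA_integer_, length(plist))
  keep <- plist %in% matched_r
  h_p[keep] <- p$atoms$hcount[r2p[as.character(plist[keep])]]
  pat_atoms <- data.frame(
    r_idx = plist, element = r$atoms$element[plist], type = r_types[plist],
    role = roles, h_r = r$atoms$hcount[plist], h_p = h_p,
    removed = plist %in% removed, stringsAsFactors = FALSE)

  pat_bonds <- data.frame(li = integer(0), lj = integer(0), order_r = integer(0),
                          arom_r = logical(0), present_p = logical(0),
                          order_p = integer(0), arom_p = logical(0))
  chkey <- if (nrow(changed)) .bond_key(changed$a, changed$b) else character(0)
  for (k in seq_len(nrow(r$bonds))) {
    i <- r$bonds$i[k]; j <- r$bonds$j[k]
    if (!(i %in% plist && j %in% plist)) next
    ck <- match(.bond_key(i, j), chkey)
    if (!is.na(ck)) {
      pat_bonds <- rbind(pat_bonds, data.frame(
        li = loc[[as.character(i)]], lj = loc[[as.character(j)]],
        order_r = changed$order_r[ck], arom_r = changed$arom_r[ck],
        present_p = changed$present_p[ck], order_p = changed$order_p[ck],
        arom_p = changed$arom_p[ck]))
    } else {
      both_matched <- i %in% matched_r && j %in% matched_r
      pat_bonds <- rbind(pat_bonds, data.frame(
        li = loc[[as.character(i)]], lj = loc[[as.character(j)]],
        order_r = r$bonds$order[k], arom_r = r$bonds$aromatic[k],
        present_p = both_matched, order_p = if (both_matched) r$bonds$order[k] else NA_integer_,
        arom_p = if (both_matched) r$bonds$aromatic[k] else FALSE))
    }
  }
  if (nrow(changed)) {      # created bonds (order_r is NA)
    for (ck in which(is.na(changed$order_r))) {
      pat_bonds <- rbind(pat_bonds, data.frame(
        li = loc[[as.character(changed$a[ck])]],
        lj = loc[[as.character(changed$b[ck])]],
        order_r = NA_integer_, arom_r = FALSE, present_p = TRUE,
        order_p = changed$order_p[ck], arom_p = changed$arom_p[ck]))
    }
  }

  frag <- list(atoms = data.frame(element = character(0), charge = integer(0),
                                  hcount = integer(0)),
               bonds = data.frame(fi = integer(0), fj = integer(0),
                                  order = integer(0), aromatic = logical(0)),
               attach = data.frame(fatom = integer(0), patom = integer(0),
                                   order = integer(0), aromatic = logical(0)))
  if (length(frag_p)) {
    frag_p <- sort(frag_p)
    floc <- stats::setNames(seq_along(frag_p), frag_p)
    frag$atoms <- data.frame(element = p$atoms$element[frag_p],
                             charge = p$atoms$charge[frag_p],
                             hcount = p$atoms$hcount[frag_p],
                             stringsAsFactors = FALSE)
    fb <- p$bonds[p$bonds$i %in% frag_p & p$bonds$j %in% frag_p, , drop = FALSE]
    frag$bonds <- data.frame(fi = as.integer(floc[as.character(fb$i)]),
                             fj = as.integer(floc[as.character(fb$j)]),
                             order = fb$order, aromatic = fb$aromatic)
    if (nrow(attach)) {
      fa <- ifelse(attach$i %in% frag_p, attach$i, attach$j)
      frag$attach <- data.frame(fatom = as.integer(floc[as.character(fa)]),
                                patom = as.integer(loc[as.character(anchors_r)]),
                                order = attach$order, aromatic = attach$aromatic)
    }
  }

  p_center <- r2p[[as.character(center)]]
  adj_p <- .adjacency(p)
  rule <- structure(list(
    key = key,
    product_rc_type = p_types[p_center],
    product_adjacent_types = sort(p_types[adj_p[[p_center]]]),
    pattern = list(atoms = pat_atoms, bonds = pat_bonds),
    fragment = frag,
    enzymes = sort(unique(rec$enzyme)), phase = rec$phase,
    provenance = rec$id), class = "transformation_rule")
  list(key = key, rule = rule)
}

#' @export
print.transformation_rule <- function(x, ...) {
  cat(sprintf("<transformation_rule> phase %s key %s -> %s; +%d atom(s), -%d atom(s); enzymes: %s\n",
              x$phase, key_string(x$key), x$product_rc_type,
              nrow(x$fragment$atoms), sum(x$pattern$atoms$removed),
              paste(x$enzymes, collapse = ",")))
  invisible(x)
}

# structural signature ignoring enzymes/provenance, for deduplication
.rule_signature <- function(rule) {
  paste(key_string(rule$key), rule$product_rc_type,
        paste(unlist(rule$pattern$atoms[c("element", "type", "role", "h_r",
                                          "h_p", "removed")]), collapse = ","),
        paste(unlist(rule$pattern$bonds), collapse = ","),
        paste(unlist(rule$fragment), collapse = ","), sep = "#")
}

# ---------------------------------------------------------------------------
# Tables

.new_table <- function(phase) {
  structure(list(phase = phase, entries = list()), class = "lookup_table")
}

.table_add <- function(tab, key, rule) {
  ks <- key_string(key)
  entry <- tab$entries[[ks]]
  if (is.null(entry)) entry <- list(key = key, rules = list())
  sig <- .rule_signature(rule)
  sigs <- vapply(entry$rules, .rule_signature, character(1))
  hit <- match(sig, sigs)
  if (!is.na(hit)) {
    entry$rules[[hit]]$enzymes <-
      sort(unique(c(entry$rules[[hit]]$enzymes, rule$enzymes)))
    entry$rules[[hit]]$provenance <-
      paste(sort(unique(c(strsplit(entry$rules[[hit]]$provenance, ";")[[1]],
                          rule$provenance))), collapse = ";")
  } else {
    entry$rules[[length(entry$rules) + 1L]] <- rule
  }
  tab$entries[[ks]] <- entry
  tab
}

#' @export
print.lookup_table <- function(x, ...) {
  cat(sprintf("<lookup_table> phase %s: %d keys, %d rules\n", x$phase,
              length(x$entries),
              sum(vapply(x$entries, function(e) length(e$rules), integer(1)))))
  invisible(x)
}

#' Build Phase I and Phase II lookup tables from reaction records
#'
#' Every record contributes one entry per reaction center; structurally
#' identical rules under the same key merge their enzyme annotations.
#' Records or centers whose rules cannot be extracted (non-local patterns,
#' fallback types, empty alignments) are skipped and reported in the
#' diagnostics, never fatally.
#'
#' @param records list of `reaction_record` objects.
#' @return list with `phase1`, `phase2` (class `lookup_table`) and
#'   `diagnostics` (data frame of skipped centers with messages).
#' @export
build_tables <- function(records) {
  if (!length(records)) stop("no reaction records supplied")
  t1 <- .new_table("I"); t2 <- .new_table("II")
  diag <- data.frame(record = character(0), center = integer(0),
                     message = character(0), stringsAsFactors = FALSE)
  for (rec in records) {
    r <- perceive_aromaticity(rec$reactant); p <- perceive_aromaticity(rec$product)
    a <- max_common_subgraph(r, p)
    centers <- find_reaction_centers(a, assign_types(r), assign_types(p))
    if (!length(centers)) {
      diag <- rbind(diag, data.frame(record = rec$id, center = NA_integer_,
                                     message = "no reaction center"))
      next
    }
    for (ct in centers) {
      res <- tryCatch(extract_rule(rec, ct, a), error = function(e) e)
      if (inherits(res, "error")) {
        diag <- rbind(diag, data.frame(record = rec$id, center = ct,
                                       message = conditionMessage(res)))
      } else if (rec$phase == "I") {
        t1 <- .table_add(t1, res$key, res$rule)
      } else {
        t2 <- .table_add(t2, res$key, res$rule)
      }
    }
  }
  list(phase1 = t1, phase2 = t2, diagnostics = diag)
}

# ---------------------------------------------------------------------------
# Serialization

.TABLE_SCHEMA <- 1L

#' Save lookup tables to JSON
#'
#' Deterministic, schema-versioned serialization: building tables twice
#' from the same records yields byte-identical files.
#'
#' @param tables list with `phase1` and `phase2` lookup tables.
#' @param path output file.
#' @export
save_tables <- function(tables, path) {
  ser_tab <- function(tab) {
    ks <- sort(names(tab$entries))
    list(phase = tab$phase, keys = lapply(ks, function(k) {
      e <- tab$entries[[k]]
      ord <- order(vapply(e$rules, .rule_signature, character(1)))
      list(key = e$key[c("rc", "adjacent", "distant")],
           rules = lapply(e$rules[ord], function(rule) {
             rule$key <- rule$key[c("rc", "adjacent", "distant")]
             unclass(rule)
           }))
    }))
  }
  obj <- list(schema = .TABLE_SCHEMA,
              phase1 = ser_tab(tables$phase1), phase2 = ser_tab(tables$phase2))
  json <- jsonlite::toJSON(obj, dataframe = "columns", auto_unbox = TRUE,
                           digits = NA, null = "null", na = "null", pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Load lookup tables from JSON
#'
#' @param path file written by [save_tables()].
#' @return list with `phase1` and `phase2` lookup tables.
#' @export
load_tables <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("cannot parse table file: ",
                                           conditionMessage(e)))
  if (is.null(obj$schema) || obj$schema != .TABLE_SCHEMA)
    stop("table schema version mismatch: expected ", .TABLE_SCHEMA,
         ", found ", if (is.null(obj$schema)) "none" else obj$schema)
  de_key <- function(k) structure(list(rc = k$rc,
                                       adjacent = as.character(unlist(k$adjacent)),
                                       distant = as.character(unlist(k$distant))),
                                  class = "lookup_key")
  de_df <- function(x, logical_cols = character(0), int_cols = character(0)) {
    if (!length(x) || all(vapply(x, length, integer(1)) == 0L)) {
      df <- as.data.frame(stats::setNames(rep(list(logical(0)), length(x)),
                                          names(x)))
      for (cl in int_cols) if (cl %in% names(df)) df[[cl]] <- integer(0)
      return(df)
    }
    df <- as.data.frame(lapply(x, function(col)
      unlist(lapply(col, function(v) if (is.null(v)) NA else v))),
      stringsAsFactors = FALSE)
    for (cl in logical_cols) if (cl %in% names(df)) df[[cl]] <- as.logical(df[[cl]])
    for (cl in int_cols) if (cl %in% names(df)) df[[cl]] <- as.integer(df[[cl]])
    df
  }
  de_tab <- function(t) {
    tab <- .new_table(t$phase)
    for (ke in t$keys) {
      key <- de_key(ke$key)
      for (rl in ke$rules) {
        rule <- structure(list(
          key = de_key(rl$key),
          product_rc_type = rl$product_rc_type,
          product_adjacent_types = as.character(unlist(rl$product_adjacent_types)),
          pattern = list(
            atoms = de_df(rl$pattern$atoms, "removed", c("r_idx", "h_r", "h_p")),
            bonds = de_df(rl$pattern$bonds, c("arom_r", "present_p", "arom_p"),
                          c("li", "lj", "order_r", "order_p"))),
          fragment = list(
            atoms = de_df(rl$fragment$atoms, character(0), c("charge", "hcount")),
            bonds = de_df(rl$fragment$bonds, "aromatic", c("fi", "fj", "order")),
            attach = de_df(rl$fragment$attach, "aromatic",
                           c("fatom", "patom", "order"))),
          enzymes = as.character(unlist(rl$enzymes)), phase = rl$phase,
          provenance = rl$provenance), class = "transformation_rule")
        tab <- .table_add(tab, key, rule)
      }
    }
    tab
  }
  list(phase1 = de_tab(obj$phase1), phase2 = de_tab(obj$phase2))
}
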