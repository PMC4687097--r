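# KEGG atom typing.
#
# Reference pipelines obtain atom types from the KEGG API; here a
# data-driven decision table (inst/extdata/kegg_atom_types.yaml) assigns a
# documented subset of the KEGG codes.  Typing is a pure function of the
# molecular graph, so re-typing an unchanged graph is always identical and
# the type multiset is invariant under atom relabeling.

.type_table_env <- new.env(parent = emptyenv())

#' Load the atom-type decision table
#'
#' @param path YAML file; defaults to the packaged table.
#' @return a list of rules (invisibly cached for the default path).
#' @export
load_type_table <- function(path = NULL) {
  default <- is.null(path)
  if (default && !is.null(.type_table_env$table)) return(.type_table_env$table)
  if (is.null(path))
    path <- system.file("extdata", "kegg_atom_types.yaml", package = "proximal")
  tab <- yaml::read_yaml(path)$types
  if (default) .type_table_env$table <- tab
  tab
}

.is_carboxyl_c <- function(g, a, adj, dblpart) {
  if (g$atoms$element[a] != "C") return(FALSE)
  has_dbl_o <- any(g$atoms$element[dblpart[[a]]] == "O")
  sing <- setdiff(adj[[a]], dblpart[[a]])
  has_dbl_o && any(g$atoms$element[sing] == "O")
}

#' Assign KEGG atom types
#'
#' Every heavy atom receives exactly one code from the decision table; atoms
#' in environments the table does not cover receive the flagged fallback
#' `"<Element>?"`, which never participates in pattern matching.
#'
#' @param g a `molgraph` (aromaticity is perceived if not yet done).
#' @param table decision table from [load_type_table()].
#' @return character vector of type codes, one per atom.
#' @export
assign_types <- function(g, table = load_type_table()) {
  if (is.null(attr(g, "ring_atoms"))) g <- perceive_aromaticity(g)
  n <- nrow(g$atoms)
  adj <- .adjacency(g)
  ring <- attr(g, "ring_atoms")
  arom_atom <- logical(n)
  dblpart <- vector("list", n)
  if (nrow(g$bonds)) for (k in seq_len(nrow(g$bonds))) {
    i <- g$bonds$i[k]; j <- g$bonds$j[k]
    if (g$bonds$aromatic[k]) arom_atom[c(i, j)] <- TRUE
    if (g$bonds$order[k] >= 2L) {
      dblpart[[i]] <- c(dblpart[[i]], j); dblpart[[j]] <- c(dblpart[[j]], i)
    }
  }
  carboxyl_c <- vapply(seq_len(n), .is_carboxyl_c, logical(1),
                       g = g, adj = adj, dblpart = dblpart)
  out <- character(n)
  for (a in seq_len(n)) {
    el <- g$atoms$element[a]
    deg <- length(adj[[a]])
    h <- g$atoms$hcount[a]
    code <- paste0(el, "?")
    for (rule in table) {
      if (!(el %in% rule$element)) next
      if (!is.null(rule$aromatic) && rule$aromatic != arom_atom[a]) next
      if (!is.null(rule$ring) && rule$ring != ring[a]) next
      if (!is.null(rule$degree) && rule$degree != deg) next
      if (!is.null(rule$h_min) && h < rule$h_min) next
      if (!is.null(rule$h_max) && h > rule$h_max) next
      if (!is.null(rule$dbl_to) &&
          !any(g$atoms$element[dblpart[[a]]] %in% rule$dbl_to)) next
      if (!is.null(rule$carboxyl)) {
        is_cx <- if (el == "C") carboxyl_c[a]
                 else any(carboxyl_c[adj[[a]]])
        if (rule$carboxyl != is_cx) next
      }
      if (!is.null(rule$attached_to)) {
        sing <- setdiff(adj[[a]], dblpart[[a]])
        if (!any(g$atoms$element[sing] %in% rule$attached_to)) next
      }
      code <- rule$code
      break
    }
    out[a] <- code
  }
  out
}

#' Typed-atom table for a molecule
#'
#' @param g a `molgraph`.
#' @return data frame with columns `index`, `element`, `kegg_type`.
#' @export
typed_atoms <- function(g) {
  g <- perceive_aromaticity(g)
  data.frame(index = seq_len(nrow(g$atoms)), element = g$atoms$element,
             kegg_type = assign_types(g), stringsAsFactors = FALSE)
}

.is_fallback_type <- function(type) grepl("?", type, fixed = TRUE)
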