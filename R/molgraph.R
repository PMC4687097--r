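#' @importFrom utils head tail
NULL

# Standard valences used to derive implicit hydrogen counts from a Kekule
# bond-order assignment.  Sulfur and phosphorus are hypervalent-tolerant:
# the smallest admissible valence >= the bond-order sum is used.
.VALENCES <- list(
  C = 4L, N = 3L, O = 2L, S = c(2L, 4L, 6L), P = c(3L, 5L),
  F = 1L, Cl = 1L, Br = 1L, I = 1L, B = 3L, Si = 4L, Se = c(2L, 4L, 6L),
  H = 1L
)

.default_valence <- function(element, charge, order_sum) {
  v <- .VALENCES[[element]]
  if (is.null(v)) return(NA_integer_)
  # Simple charge adjustment for organic subset: N+ -> 4, O- -> 1, O+ -> 3,
  # N- -> 2, C+/C- -> 3.  Fixture molecules are neutral.
  if (charge != 0L) {
    adj <- switch(element,
      N = 3L + charge, O = 2L + charge, C = 4L - abs(charge),
      S = 2L + charge, v[1]
    )
    return(max(adj, 0L))
  }
  v <- v[v >= order_sum]
  if (length(v) == 0L) return(NA_integer_)
  v[1]
}

#' Construct a molecular graph
#'
#' The central container of the package: a heavy-atom graph with Kekule bond
#' orders, per-atom implicit hydrogen counts and formal charges, following
#' MDL molfile semantics.  Atom indices are contiguous `1..N` in input order.
#'
#' @param elements character vector of element symbols.
#' @param bonds data frame (or 3-column matrix) with columns `i`, `j`,
#'   `order` (1, 2 or 3); an optional logical `aromatic` column is accepted.
#' @param charges integer vector of formal charges (default all zero).
#' @param hcount integer vector of implicit hydrogen counts; if `NULL`,
#'   computed from standard valences and the Kekule bond orders.
#' @param name,source_id free-text identity metadata.
#' @return an object of class `molgraph`.
#' @export
molgraph <- function(elements, bonds, charges = NULL, hcount = NULL,
                     name = "", source_id = "") {
  n <- length(elements)
  if (n == 0L) stop("molecule must contain at least one heavy atom")
  bad <- setdiff(elements, names(.VALENCES))
  if (length(bad)) stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  if (is.null(charges)) charges <- integer(n)
  if (is.null(bonds) || NROW(bonds) == 0L) {
    bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0),
                        aromatic = logical(0))
  } else {
    bonds <- as.data.frame(bonds)
    if (is.null(bonds$aromatic)) bonds$aromatic <- FALSE
    bonds <- bonds[, c("i", "j", "order", "aromatic")]
    swap <- bonds$i > bonds$j
    tmp <- bonds$i[swap]; bonds$i[swap] <- bonds$j[swap]; bonds$j[swap] <- tmp
    if (any(bonds$i == bonds$j)) stop("self-bonds are not allowed")
    if (any(bonds$i < 1L | bonds$j > n)) stop("bond endpoint outside atom range")
    if (anyDuplicated(bonds[, c("i", "j")])) stop("duplicate bond")
    bonds <- bonds[order(bonds$i, bonds$j), , drop = FALSE]
    rownames(bonds) <- NULL
  }
  g <- structure(list(
    atoms = data.frame(element = elements, charge = as.integer(charges),
                       hcount = NA_integer_, stringsAsFactors = FALSE),
    bonds = bonds, name = name, source_id = source_id
  ), class = "molgraph")
  g$atoms$hcount <- if (is.null(hcount)) .implicit_h(g) else as.integer(hcount)
  g
}

.order_sums <- function(g) {
  s <- numeric(nrow(g$atoms))
  if (nrow(g$bonds)) {
    for (k in seq_len(nrow(g$bonds))) {
      s[g$bonds$i[k]] <- s[g$bonds$i[k]] + g$bonds$order[k]
      s[g$bonds$j[k]] <- s[g$bonds$j[k]] + g$bonds$order[k]
    }
  }
  s
}

.implicit_h <- function(g) {
  os <- .order_sums(g)
  vapply(seq_len(nrow(g$atoms)), function(a) {
    v <- .default_valence(g$atoms$element[a], g$atoms$charge[a], os[a])
    if (is.na(v)) return(0L)
    max(v - as.integer(os[a]), 0L)
  }, integer(1))
}

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph> %s%s: %d atoms, %d bonds, formula %s\n",
              if (nzchar(x$name)) x$name else "(unnamed)",
              if (nzchar(x$source_id)) paste0(" [", x$source_id, "]") else "",
              nrow(x$atoms), nrow(x$bonds), mol_formula(x)))
  invisible(x)
}

#' Hill-order molecular formula (including implicit hydrogens)
#' @param g a `molgraph`.
#' @return a character scalar such as `"C15H16O2"`.
#' @export
mol_formula <- function(g) {
  counts <- table(g$atoms$element)
  h <- sum(g$atoms$hcount)
  els <- names(counts)
  ord <- c(intersect(c("C", "H"), c(els, if (h > 0) "H")),
           sort(setdiff(els, c("C", "H"))))
  if (h > 0 && !("H" %in% els)) counts <- c(counts, H = h)
  paste0(vapply(ord, function(e) {
    k <- as.integer(counts[[e]])
    paste0(e, if (k > 1L) k else "")
  }, character(1)), collapse = "")
}

# Adjacency list: integer vector of neighbors per atom.
.adjacency <- function(g) {
  n <- nrow(g$atoms)
  adj <- vector("list", n)
  for (k in seq_len(nrow(g$bonds))) {
    i <- g$bonds$i[k]; j <- g$bonds$j[k]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  lapply(adj, function(v) if (is.null(v)) integer(0) else sort(v))
}

.bond_lookup <- function(g) {
  # named list "i-j" -> row index into g$bonds (i < j); [[ ]] on a missing
  # key must return NULL, hence a list rather than a named vector
  if (!nrow(g$bonds)) return(list())
  as.list(stats::setNames(seq_len(nrow(g$bonds)),
                          paste(g$bonds$i, g$bonds$j, sep = "-")))
}

.bond_key <- function(i, j) paste(pmin(i, j), pmax(i, j), sep = "-")

# ---------------------------------------------------------------------------
# MDL molfile V2000 I/O

#' Read a V2000 molfile
#'
#' Parses an MDL molfile (V2000 connection table) into a [molgraph()].
#' Explicit hydrogen atoms are folded into the implicit hydrogen count of
#' their heavy neighbor; wedge/stereo annotations are parsed and discarded
#' (the transformation patterns of this package are constitution-only).
#' V3000 records are rejected.
#'
#' @param text molfile content: a single string or a character vector of
#'   lines; alternatively the path of a file (detected when `text` is a
#'   single line naming an existing file).
#' @param name optional molecule name override (default: molfile title line).
#' @return a `molgraph` with aromaticity perceived ([perceive_aromaticity()]).
#' @export
read_molfile <- function(text, name = NULL) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    lines <- readLines(text, warn = FALSE)
  } else {
    lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  }
  if (length(lines) < 4L) stop("molfile too short: no counts line (line 4)")
  counts <- lines[4]
  if (grepl("V3000", counts)) stop("V3000 molfiles are not supported (line 4); supply V2000")
  natoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(natoms) || is.na(nbonds))
    stop("malformed counts line (line 4): ", sQuote(counts))
  mend <- grep("^M  END", lines)[1]
  avail <- (if (!is.na(mend)) mend - 1L else length(lines)) - 4L
  if (natoms + nbonds > avail)
    stop(sprintf("counts line declares %d atoms and %d bonds but only %d connection-table lines follow",
                 natoms, nbonds, avail))
  elements <- character(natoms); charges <- integer(natoms)
  for (a in seq_len(natoms)) {
    ln <- lines[4L + a]
    el <- trimws(substr(ln, 32, 34))
    if (!nzchar(el)) {
      # tolerate whitespace-separated atom lines
      parts <- strsplit(trimws(ln), "\\s+")[[1]]
      el <- if (length(parts) >= 4L) parts[4] else ""
    }
    if (!nzchar(el)) stop("malformed atom line ", 4L + a)
    if (!(el %in% c(names(.VALENCES))))
      stop("unknown element symbol ", sQuote(el), " on line ", 4L + a)
    elements[a] <- el
    chg <- suppressWarnings(as.integer(substr(ln, 37, 39)))
    if (!is.na(chg) && chg != 0L) charges[a] <- c(3L, 2L, 1L, 0L, -1L, -2L, -3L)[chg]
  }
  bi <- integer(nbonds); bj <- integer(nbonds); bo <- integer(nbonds)
  for (b in seq_len(nbonds)) {
    ln <- lines[4L + natoms + b]
    i <- suppressWarnings(as.integer(substr(ln, 1, 3)))
    j <- suppressWarnings(as.integer(substr(ln, 4, 6)))
    o <- suppressWarnings(as.integer(substr(ln, 7, 9)))
    if (any(is.na(c(i, j, o)))) stop("malformed bond line ", 4L + natoms + b)
    if (i < 1L || j < 1L || i > natoms || j > natoms)
      stop("bond endpoint out of range on line ", 4L + natoms + b)
    if (o == 4L)
      stop("aromatic bond order 4 on line ", 4L + natoms + b,
           ": supply a Kekule structure")
    if (!(o %in% 1:3)) stop("unsupported bond order ", o, " on line ", 4L + natoms + b)
    bi[b] <- i; bj[b] <- j; bo[b] <- o
  }
  # M  CHG overrides the atom-block charge column
  for (ln in lines[-seq_len(4L + natoms + nbonds)]) {
    if (startsWith(ln, "M  CHG")) {
      toks <- as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))), "\\s+")[[1]])
      cnt <- toks[1]
      charges[] <- 0L
      for (k in seq_len(cnt)) charges[toks[2 * k]] <- toks[2 * k + 1]
    }
    if (startsWith(ln, "M  END")) break
  }
  title <- trimws(lines[1])
  g <- molgraph(elements, data.frame(i = bi, j = bj, order = bo),
                charges = charges,
                name = if (is.null(name)) title else name, source_id = title)
  g <- .fold_explicit_h(g)
  perceive_aromaticity(g)
}

# Remove explicit H atoms, crediting them to the implicit count of their
# heavy neighbor.  Isolated H (e.g. H2) is rejected.
.fold_explicit_h <- function(g) {
  hs <- which(g$atoms$element == "H")
  if (!length(hs)) return(g)
  adj <- .adjacency(g)
  extra <- integer(nrow(g$atoms))
  for (h in hs) {
    nb <- setdiff(adj[[h]], hs)
    if (length(nb) != 1L)
      stop("explicit hydrogen atom ", h, " is not bonded to exactly one heavy atom")
    extra[nb] <- extra[nb] + 1L
  }
  keep <- setdiff(seq_len(nrow(g$atoms)), hs)
  remap <- match(seq_len(nrow(g$atoms)), keep)
  b <- g$bonds[!(g$bonds$i %in% hs | g$bonds$j %in% hs), , drop = FALSE]
  b$i <- remap[b$i]; b$j <- remap[b$j]
  g2 <- molgraph(g$atoms$element[keep], b, charges = g$atoms$charge[keep],
                 name = g$name, source_id = g$source_id)
  g2$atoms$hcount <- g2$atoms$hcount  # valence-derived already counts folded H
  g2
}

#' Write a V2000 molfile
#'
#' Emits the molecule as an MDL V2000 connection table with zeroed 2D
#' coordinates, preserving atom order.  Newly added atoms of predicted
#' products always appear after the atoms of the query molecule.
#'
#' @param g a `molgraph`.
#' @param path optional file path; when `NULL` the text is returned.
#' @return the molfile text, invisibly when written to `path`.
#' @export
write_molfile <- function(g, path = NULL) {
  stopifnot(inherits(g, "molgraph"))
  if (nrow(g$atoms) == 0L) stop("refusing to write an empty molecule")
  if (nrow(g$atoms) > 999L) stop("V2000 supports at most 999 atoms")
  lines <- c(g$name, "  proximal", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                     nrow(g$atoms), nrow(g$bonds)))
  for (a in seq_len(nrow(g$atoms))) {
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              0, 0, 0, g$atoms$element[a]))
  }
  for (b in seq_len(nrow(g$bonds))) {
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                              g$bonds$i[b], g$bonds$j[b], g$bonds$order[b]))
  }
  chg <- which(g$atoms$charge != 0L)
  if (length(chg)) {
    lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(chg)),
                             paste0(sprintf("%4d%4d", chg, g$atoms$charge[chg]),
                                    collapse = "")))
  }
  lines <- c(lines, "M  END")
  out <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) { writeLines(out, path, sep = ""); return(invisible(out)) }
  out
}

#' Read a molecule from a SMILES string
#'
#' Convenience wrapper: the SMILES is converted to a Kekule V2000 molblock
#' with ChemmineR/ChemmineOB (Open Babel) and parsed with [read_molfile()],
#' so the resulting graph model is identical to molfile input.  Atom order
#' is the converter's traversal order and is not canonical.
#'
#' @param smiles a single SMILES string.
#' @param name molecule name.
#' @return a `molgraph`.
#' @export
read_smiles <- function(smiles, name = smiles) {
  if (!requireNamespace("ChemmineR", quietly = TRUE) ||
      !requireNamespace("ChemmineOB", quietly = TRUE))
    stop("read_smiles requires the ChemmineR and ChemmineOB packages")
  sdf <- ChemmineR::smiles2sdf(smiles)
  block <- as(sdf[[1]], "character")
  block <- block[seq_len(max(grep("^M  END", block)))]
  read_molfile(block, name = name)
}

# ---------------------------------------------------------------------------
# Canonical identity and isomorphism

# igraph encoding with a subdivision vertex per bond so that bond classes
# participate in vertex-colored algorithms.  Aromatic bonds form one class
# regardless of their Kekule order, so alternative Kekule renderings of the
# same aromatic system compare equal.
.igraph_encode <- function(g) {
  n <- nrow(g$atoms)
  acolor <- paste(g$atoms$element, g$atoms$charge, g$atoms$hcount, sep = "/")
  bclass <- ifelse(g$bonds$aromatic, "a", as.character(g$bonds$order))
  m <- nrow(g$bonds)
  ig <- igraph::make_empty_graph(n + m, directed = FALSE)
  if (m) {
    bv <- n + seq_len(m)
    edges <- as.vector(rbind(c(g$bonds$i, bv), c(bv, g$bonds$j)))
    ig <- igraph::add_edges(ig, edges)
  }
  list(graph = ig, colors = c(acolor, paste0("bond:", bclass)), natoms = n)
}

#' Canonical identity key of a molecule
#'
#' A string that is identical for isomorphic molecular graphs (same
#' elements, charges, hydrogen counts and bond classes, with aromatic bonds
#' forming a single class) and different otherwise.  Computed from a BLISS
#' canonical vertex ordering, so it is exact and deterministic; used to
#' deduplicate predicted products generated at symmetry-equivalent sites.
#'
#' @param g a `molgraph`.
#' @return a character scalar.
#' @export
canonical_key <- function(g) {
  enc <- .igraph_encode(g)
  cols <- as.integer(factor(enc$colors, levels = sort(unique(enc$colors))))
  perm <- igraph::canonical_permutation(enc$graph, colors = cols)$labeling
  cg <- igraph::permute(enc$graph, perm)
  lab <- character(length(cols)); lab[perm] <- enc$colors
  el <- igraph::as_edgelist(cg)
  el <- el[order(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])), , drop = FALSE]
  paste(paste(lab, collapse = ";"),
        paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]),
              sep = "-", collapse = ";"),
        sep = "|")
}

#' Test two molecules for graph isomorphism
#'
#' VF2 isomorphism on (element, charge, hydrogen count) vertex colors and
#' bond classes (aromatic bonds one class).  Independent of
#' [canonical_key()], which uses a canonical-ordering algorithm; the two
#' agree on all fixtures and that agreement is exercised in the tests.
#'
#' @param g1,g2 `molgraph` objects.
#' @return logical.
#' @export
graph_isomorphic <- function(g1, g2) {
  if (nrow(g1$atoms) != nrow(g2$atoms) || nrow(g1$bonds) != nrow(g2$bonds))
    return(FALSE)
  e1 <- .igraph_encode(g1); e2 <- .igraph_encode(g2)
  lev <- sort(unique(c(e1$colors, e2$colors)))
  c1 <- as.integer(factor(e1$colors, levels = lev))
  c2 <- as.integer(factor(e2$colors, levels = lev))
  if (!identical(sort(c1), sort(c2))) return(FALSE)
  igraph::isomorphic(e1$graph, e2$graph, method = "vf2",
                     vertex.color1 = c1, vertex.color2 = c2)
}

# Plain heavy-atom igraph (no subdivision), for paths/components.
.igraph_skeleton <- function(g) {
  ig <- igraph::make_empty_graph(nrow(g$atoms), directed = FALSE)
  if (nrow(g$bonds)) ig <- igraph::add_edges(ig, as.vector(rbind(g$bonds$i, g$bonds$j)))
  ig
}

# ---------------------------------------------------------------------------
# Structural editing helpers (used by rule application and fixtures)

# Apply a batch edit and return the result as a fresh molgraph plus the
# index map old -> new (NA for deleted atoms).
.edit_graph <- function(g, delete_atoms = integer(0), set_bonds = NULL,
                        add_atoms = NULL, add_bonds = NULL, set_h = NULL) {
  elements <- g$atoms$element; charges <- g$atoms$charge; h <- g$atoms$hcount
  bonds <- g$bonds
  if (!is.null(set_bonds) && NROW(set_bonds)) {
    mk_lk <- function(b) as.list(stats::setNames(seq_len(nrow(b)),
                                                 paste(b$i, b$j, sep = "-")))
    lk <- mk_lk(bonds)
    for (r in seq_len(nrow(set_bonds))) {
      key <- .bond_key(set_bonds$i[r], set_bonds$j[r])
      row <- lk[[key]]
      if (set_bonds$order[r] == 0L) {
        if (!is.null(row)) bonds <- bonds[-row, , drop = FALSE]
        lk <- mk_lk(bonds)
      } else if (is.null(row)) {
        bonds <- rbind(bonds, data.frame(i = min(set_bonds$i[r], set_bonds$j[r]),
                                         j = max(set_bonds$i[r], set_bonds$j[r]),
                                         order = set_bonds$order[r],
                                         aromatic = isTRUE(set_bonds$aromatic[r])))
        lk <- mk_lk(bonds)
      } else {
        bonds$order[row] <- set_bonds$order[r]
        bonds$aromatic[row] <- isTRUE(set_bonds$aromatic[r])
      }
    }
  }
  nold <- length(elements)
  if (!is.null(add_atoms) && NROW(add_atoms)) {
    elements <- c(elements, add_atoms$element)
    charges <- c(charges, if (is.null(add_atoms$charge)) integer(nrow(add_atoms)) else add_atoms$charge)
    h <- c(h, add_atoms$hcount)
  }
  if (!is.null(add_bonds) && NROW(add_bonds)) {
    bonds <- rbind(bonds, data.frame(i = add_bonds$i, j = add_bonds$j,
                                     order = add_bonds$order,
                                     aromatic = if (is.null(add_bonds$aromatic))
                                       FALSE else add_bonds$aromatic))
  }
  if (!is.null(set_h) && length(set_h)) {
    for (nm in names(set_h)) h[as.integer(nm)] <- set_h[[nm]]
  }
  keep <- setdiff(seq_along(elements), delete_atoms)
  remap <- match(seq_along(elements), keep)
  bonds <- bonds[!(bonds$i %in% delete_atoms | bonds$j %in% delete_atoms), , drop = FALSE]
  bonds$i <- remap[bonds$i]; bonds$j <- remap[bonds$j]
  g2 <- molgraph(elements[keep], bonds, charges = charges[keep],
                 hcount = h[keep], name = g$name, source_id = g$source_id)
  list(graph = g2, map = remap[seq_len(nold)],
       new_atoms = remap[setdiff(seq_along(elements), seq_len(nold))])
}

# Valence consistency check: every atom must satisfy an admissible valence
# exactly (bond-order sum + implicit H).  Returns TRUE or a message.
.check_valences <- function(g) {
  os <- .order_sums(g)
  for (a in seq_len(nrow(g$atoms))) {
    el <- g$atoms$element[a]; ch <- g$atoms$charge[a]
    tot <- os[a] + g$atoms$hcount[a]
    v <- .VALENCES[[el]]
    ok <- if (ch == 0L) tot %in% v else tot == .default_valence(el, ch, os[a])
    if (!ok) return(sprintf("atom %d (%s) has valence %d", a, el, tot))
  }
  TRUE
}
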