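# Reactant-product atom alignment by maximum common connected subgraph,
# the role the SIMCOMP service plays in the original pipeline.  Atoms may
# align only when elements match; bond orders are ignored during matching
# (oxidation-state changes at the center would otherwise break the
# alignment) and compared afterwards during rule extraction.  The aligned
# subgraph is connected and every reactant bond between aligned atoms must
# be present between their images (subgraph monomorphism); the search is
# run in both directions and the larger alignment kept, which makes the
# score symmetric in the two molecules.

# Greedy seed: identity-index alignment over the longest valid connected
# prefix.  Reaction pairs share their leading atoms in file order, so this
# usually starts at (or near) the optimum and the bound prunes hard.
.identity_seed <- function(el_r, el_p, Ar, Ap) {
  seed <- integer(0)
  for (i in seq_len(min(length(el_r), length(el_p)))) {
    if (el_r[i] != el_p[i]) break
    ok <- TRUE
    for (a in seed) if (Ar[i, a] && !Ap[i, a]) { ok <- FALSE; break }
    if (!ok) break
    if (length(seed) && !any(Ar[i, seed])) break   # keep it connected
    seed <- c(seed, i)
  }
  seed
}

# One-directional search: connected subgraph of `r` embedded into `p`.
.mcs_dir <- function(r, p, node_budget) {
  nr <- nrow(r$atoms); np <- nrow(p$atoms)
  maxk <- min(nr, np)
  adj_r <- .adjacency(r); adj_p <- .adjacency(p)
  Ar <- matrix(FALSE, nr, nr); for (a in seq_len(nr)) Ar[a, adj_r[[a]]] <- TRUE
  Ap <- matrix(FALSE, np, np); for (a in seq_len(np)) Ap[a, adj_p[[a]]] <- TRUE
  el_r <- r$atoms$element; el_p <- p$atoms$element
  lev <- sort(unique(c(el_r, el_p)))
  code_r <- match(el_r, lev); code_p <- match(el_p, lev)
  compat <- outer(el_r, el_p, "==")
  st <- new.env(parent = emptyenv())
  st$best_r <- integer(0); st$best_p <- integer(0)
  st$best_size <- 0L; st$nodes <- 0L; st$exact <- TRUE; st$done <- FALSE
  seed <- .identity_seed(el_r, el_p, Ar, Ap)
  if (length(seed) > 1L) {
    st$best_r <- seed; st$best_p <- seed; st$best_size <- length(seed)
    if (st$best_size == maxk) st$done <- TRUE
  }
  # element-wise upper bound on extension: unmapped r atoms reachable from
  # the current fragment through unmapped atoms, vs unmapped p atoms
  ext_bound <- function(mr, used_p, start_i) {
    seen <- logical(nr); seen[mr] <- TRUE
    queue <- setdiff(unique(unlist(adj_r[mr])), mr)
    queue <- queue[queue >= start_i]
    reach <- integer(0)
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      if (seen[v]) next
      seen[v] <- TRUE; reach <- c(reach, v)
      nxt <- adj_r[[v]]
      queue <- c(queue, nxt[!seen[nxt] & nxt >= start_i])
    }
    if (!length(reach)) return(0L)
    tr <- tabulate(code_r[reach], length(lev))
    tp <- tabulate(code_p[!used_p], length(lev))
    sum(pmin(tr, tp))
  }
  extend <- function(mr, mp, used_p, start_i) {
    if (st$done) return()
    st$nodes <- st$nodes + 1L
    if (st$nodes > node_budget) { st$exact <- FALSE; return() }
    if (length(mr) > st$best_size) {
      st$best_r <- mr; st$best_p <- mp; st$best_size <- length(mr)
      if (st$best_size == maxk) { st$done <- TRUE; return() }
    }
    if (length(mr) + ext_bound(mr, used_p, start_i) <= st$best_size) return()
    frontier <- sort(setdiff(unique(unlist(adj_r[mr])), mr))
    frontier <- frontier[frontier >= start_i]
    for (i in frontier) {
      for (j in which(compat[i, ] & !used_p)) {
        ok <- TRUE
        for (t in seq_along(mr)) {
          if (Ar[i, mr[t]] && !Ap[j, mp[t]]) { ok <- FALSE; break }
        }
        if (!ok) next
        used_p[j] <- TRUE
        extend(c(mr, i), c(mp, j), used_p, start_i)
        used_p[j] <- FALSE
        if (st$done) return()
      }
    }
  }
  if (any(compat) && !st$done) {
    used_p <- logical(np)
    for (i0 in seq_len(nr)) {
      if (st$done || nr - i0 + 1L <= st$best_size) break
      for (j0 in which(compat[i0, ])) {
        used_p[j0] <- TRUE
        extend(i0, j0, used_p, i0)
        used_p[j0] <- FALSE
        if (st$done) break
      }
    }
  }
  o <- order(st$best_r)
  list(pairs_r = st$best_r[o], pairs_p = st$best_p[o],
       score = st$best_size, exact = st$exact)
}

.as_alignment <- function(pr, pp, score, exact) {
  pairs <- matrix(c(pr, pp), ncol = 2,
                  dimnames = list(NULL, c("reactant", "product")))
  structure(list(pairs = pairs, score = score, exact = exact),
            class = "atom_alignment")
}

#' Align two molecules by their largest common substructure
#'
#' Branch-and-bound search (McGregor style) over connected common
#' subgraphs, exact for the small molecules of this domain; `node_budget`
#' caps the number of search nodes so large inputs degrade gracefully to
#' the best alignment found, mirroring the heuristic cutoffs of fast MCS
#' services.  Deterministic: candidates are enumerated in ascending index
#' order and the first maximum-size alignment encountered is kept.
#'
#' @param r,p `molgraph` reactant and product.
#' @param node_budget maximum number of search-tree nodes per direction.
#' @return an `atom_alignment`: list with `pairs` (two-column integer matrix
#'   `reactant`, `product`, ordered by reactant atom index), `score`
#'   (number of aligned atoms) and `exact` (FALSE when the budget was hit).
#' @export
max_common_subgraph <- function(r, p, node_budget = 3e5) {
  nr <- nrow(r$atoms); np <- nrow(p$atoms)
  stopifnot(nr > 0L, np > 0L)
  # probe both directions with the cheap identity seed and run the more
  # promising one first; a direction that attains min(nr, np) is final
  mk <- function(g) {
    adj <- .adjacency(g)
    A <- matrix(FALSE, nrow(g$atoms), nrow(g$atoms))
    for (a in seq_len(nrow(g$atoms))) A[a, adj[[a]]] <- TRUE
    A
  }
  Ar <- mk(r); Ap <- mk(p)
  s1 <- length(.identity_seed(r$atoms$element, p$atoms$element, Ar, Ap))
  s2 <- length(.identity_seed(p$atoms$element, r$atoms$element, Ap, Ar))
  run2_first <- s2 > s1
  first <- if (run2_first) .mcs_dir(p, r, node_budget) else .mcs_dir(r, p, node_budget)
  as_first <- function(d) {
    if (run2_first) {
      o <- order(d$pairs_p)
      .as_alignment(d$pairs_p[o], d$pairs_r[o], d$score, d$exact)
    } else .as_alignment(d$pairs_r, d$pairs_p, d$score, d$exact)
  }
  if (first$score == min(nr, np)) return(as_first(first))
  second <- if (run2_first) .mcs_dir(r, p, node_budget) else .mcs_dir(p, r, node_budget)
  as_second <- function(d) {
    if (run2_first) .as_alignment(d$pairs_r, d$pairs_p, d$score, d$exact)
    else { o <- order(d$pairs_p)
      .as_alignment(d$pairs_p[o], d$pairs_r[o], d$score, d$exact) }
  }
  if (second$score > first$score) as_second(second) else as_first(first)
}

#' @export
print.atom_alignment <- function(x, ...) {
  cat(sprintf("<atom_alignment> %d aligned atoms%s\n", x$score,
              if (!x$exact) " (budget hit; may be suboptimal)" else ""))
  invisible(x)
}

.brute_dir <- function(r, p) {
  nr <- nrow(r$atoms); np <- nrow(p$atoms)
  adj <- .adjacency(r)
  subsets <- vector("list", nr); for (k in seq_len(nr)) subsets[[k]] <- list()
  grow <- function(sub, ext, excl) {
    subsets[[length(sub)]][[length(subsets[[length(sub)]]) + 1L]] <<- sub
    while (length(ext)) {
      v <- ext[1]; ext <- ext[-1]
      newext <- c(ext, setdiff(adj[[v]], c(sub, ext, excl, v)))
      grow(c(sub, v), newext, excl)
      excl <- c(excl, v)
    }
  }
  for (v in seq_len(nr)) grow(v, setdiff(adj[[v]], seq_len(v)), seq_len(v - 1L))
  ig_p <- .igraph_skeleton(p)
  el_p <- p$atoms$element
  for (k in seq(min(nr, np), 1L)) {
    hits <- list()
    for (sub in subsets[[k]]) {
      sub <- sort(sub)
      bsub <- r$bonds[r$bonds$i %in% sub & r$bonds$j %in% sub, , drop = FALSE]
      ig_r <- igraph::make_empty_graph(k, directed = FALSE)
      if (nrow(bsub))
        ig_r <- igraph::add_edges(ig_r, as.vector(rbind(match(bsub$i, sub),
                                                        match(bsub$j, sub))))
      doms <- lapply(sub, function(a) which(el_p == r$atoms$element[a]))
      if (any(vapply(doms, length, integer(1)) == 0L)) next
      maps <- tryCatch(
        igraph::subgraph_isomorphisms(ig_r, ig_p, method = "lad",
                                      induced = FALSE, domains = doms),
        error = function(e) list())
      for (mp in maps)
        hits[[length(hits) + 1L]] <- as.vector(rbind(sub, as.integer(mp)))
    }
    if (length(hits)) {
      keys <- vapply(hits, function(h) paste(sprintf("%04d", h), collapse = ""),
                     character(1))
      best <- hits[[order(keys)[1]]]
      m <- matrix(best, ncol = 2, byrow = TRUE)
      return(list(pairs_r = m[, 1], pairs_p = m[, 2], score = k))
    }
  }
  list(pairs_r = integer(0), pairs_p = integer(0), score = 0L)
}

#' Exhaustive maximum common subgraph (test oracle)
#'
#' Enumerates every connected vertex subset of one molecule and tests it
#' for an element-compatible monomorphic embedding into the other with the
#' LAD solver, in both directions, independently of the branch-and-bound
#' search in [max_common_subgraph()].  Refuses molecules above 12 heavy
#' atoms.
#'
#' @param r,p `molgraph` objects with at most 12 heavy atoms each.
#' @return an `atom_alignment` (same fields as [max_common_subgraph()]).
#' @export
brute_force_mcs <- function(r, p) {
  nr <- nrow(r$atoms); np <- nrow(p$atoms)
  if (nr > 12L || np > 12L)
    stop("brute_force_mcs is an exhaustive oracle; both molecules must have <= 12 atoms")
  if (!any(r$atoms$element %in% p$atoms$element))
    return(.as_alignment(integer(0), integer(0), 0L, TRUE))
  d1 <- .brute_dir(r, p)
  if (d1$score < min(nr, np)) {
    d2 <- .brute_dir(p, r)
    if (d2$score > d1$score) {
      o <- order(d2$pairs_p)
      return(.as_alignment(d2$pairs_p[o], d2$pairs_r[o], d2$score, TRUE))
    }
  }
  .as_alignment(d1$pairs_r, d1$pairs_p, d1$score, TRUE)
}

#' Tabulate an alignment with atom types
#'
#' The tab-separated layout of the aligned-atom listing: one row per
#' aligned pair, ordered by reactant atom index.
#'
#' @param a an `atom_alignment`.
#' @param r,p the aligned molecules.
#' @return data frame with columns `reactant_index`, `reactant_type`,
#'   `product_index`, `product_type`.
#' @export
alignment_table <- function(a, r, p) {
  rt <- assign_types(r); pt <- assign_types(p)
  data.frame(reactant_index = a$pairs[, 1],
             reactant_type = rt[a$pairs[, 1]],
             product_index = a$pairs[, 2],
             product_type = pt[a$pairs[, 2]],
             stringsAsFactors = FALSE)
}
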