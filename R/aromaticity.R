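# Ring perception and Hueckel-style aromaticity.
#
# Rings up to size 8 are enumerated by DFS (xenobiotic fixtures are small
# molecules; fused bicyclics are covered by per-ring evaluation).  A ring is
# aromatic when every member is sp2-compatible and the pi-electron count is
# 4n + 2 (n >= 1):
#   * atom with a double bond to another ring member        -> 1 electron
#   * carbon with an exocyclic double bond to O/N/S         -> 0 electrons
#     (carbonyl-type member, as in pyrazolones and pyridones)
#   * N/O/S with only single bonds                          -> 2 electrons
#   * carbon with only single bonds                         -> not aromatic

.find_rings <- function(g, max_size = 8L) {
  n <- nrow(g$atoms)
  adj <- .adjacency(g)
  rings <- list()
  seen <- new.env(hash = TRUE)
  path <- integer(max_size)
  dfs <- function(start, v, depth, onpath) {
    for (w in adj[[v]]) {
      if (w == start && depth >= 3L) {
        ring <- path[seq_len(depth)]
        rot <- which.min(ring)
        norm <- c(ring[rot:depth], ring[seq_len(rot - 1L)])
        # canonical form: smallest rotation, direction with smaller 2nd atom
        fwd <- norm
        rev_ <- c(norm[1], rev(norm[-1]))
        canon <- if (paste(fwd, collapse = ",") <= paste(rev_, collapse = ","))
          fwd else rev_
        key <- paste(canon, collapse = ",")
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          rings[[length(rings) + 1L]] <<- canon
        }
      } else if (depth < max_size && !onpath[w] && w > start) {
        path[depth + 1L] <<- w
        onpath[w] <- TRUE
        dfs(start, w, depth + 1L, onpath)
        onpath[w] <- FALSE
      }
    }
  }
  onpath <- logical(n)
  for (s in seq_len(n)) {
    path[1] <- s
    onpath[s] <- TRUE
    dfs(s, s, 1L, onpath)
    onpath[s] <- FALSE
  }
  rings
}

#' Perceive aromaticity
#'
#' Flags ring bonds as aromatic using a Hueckel-style alternation test on
#' each ring of size up to 8 (see the package vignette for the electron
#' counting rules).  Also records ring membership of atoms and bonds, which
#' the atom-typing decision table consumes.  Deterministic; calling it again
#' on an unchanged graph is a no-op.
#'
#' @param g a `molgraph`.
#' @return `g` with `bonds$aromatic` set and attributes `ring_atoms`
#'   (logical per atom) and `ring_bonds` (logical per bond).
#' @export
perceive_aromaticity <- function(g) {
  rings <- .find_rings(g)
  n <- nrow(g$atoms); m <- nrow(g$bonds)
  ring_atoms <- logical(n); ring_bonds <- logical(m)
  aromatic <- logical(m)
  lk <- .bond_lookup(g)
  # per-atom double/triple partners
  dbl <- vector("list", n)
  if (m) for (k in seq_len(m)) {
    if (g$bonds$order[k] >= 2L) {
      dbl[[g$bonds$i[k]]] <- c(dbl[[g$bonds$i[k]]], g$bonds$j[k])
      dbl[[g$bonds$j[k]]] <- c(dbl[[g$bonds$j[k]]], g$bonds$i[k])
    }
  }
  for (ring in rings) {
    rows <- vapply(seq_along(ring), function(t) {
      lk[[.bond_key(ring[t], ring[t %% length(ring) + 1L])]]
    }, integer(1))
    ring_atoms[ring] <- TRUE
    ring_bonds[rows] <- TRUE
    pi <- 0L; ok <- TRUE
    for (a in ring) {
      partners <- dbl[[a]]
      el <- g$atoms$element[a]
      if (length(partners) && any(partners %in% ring)) {
        pi <- pi + 1L
      } else if (length(partners)) {
        # exocyclic multiple bond
        exo <- g$atoms$element[partners[1]]
        if (el == "C" && exo %in% c("O", "N", "S")) pi <- pi + 0L
        else { ok <- FALSE; break }
      } else if (el %in% c("N", "O", "S")) {
        pi <- pi + 2L
      } else { ok <- FALSE; break }
    }
    if (ok && pi >= 6L && (pi - 2L) %% 4L == 0L) aromatic[rows] <- TRUE
  }
  g$bonds$aromatic <- aromatic
  attr(g, "ring_atoms") <- ring_atoms
  attr(g, "ring_bonds") <- ring_bonds
  g
}

.ring_atoms <- function(g) {
  ra <- attr(g, "ring_atoms")
  if (is.null(ra)) { g <- perceive_aromaticity(g); ra <- attr(g, "ring_atoms") }
  ra
}

# ---------------------------------------------------------------------------
# Kekule re-solver.
#
# After a rule edit, bonds that belonged to an aromatic system but were not
# explicitly set by the rule keep correct connectivity but possibly stale
# orders.  Their orders (1 or 2) are re-derived exactly from the valence
# constraint: for every atom, bond-order sum + implicit H must equal an
# admissible valence.  Backtracking over the free bonds; atoms without free
# bonds are checked directly.  Returns the solved bond-order vector or NULL.
.solve_kekule <- function(g, free_rows) {
  orders <- g$bonds$order
  os_fixed <- numeric(nrow(g$atoms))
  if (nrow(g$bonds)) for (k in seq_len(nrow(g$bonds))) {
    if (!(k %in% free_rows)) {
      os_fixed[g$bonds$i[k]] <- os_fixed[g$bonds$i[k]] + orders[k]
      os_fixed[g$bonds$j[k]] <- os_fixed[g$bonds$j[k]] + orders[k]
    }
  }
  # residual capacity per atom = target valence - H - fixed order sum
  res <- vapply(seq_len(nrow(g$atoms)), function(a) {
    el <- g$atoms$element[a]; ch <- g$atoms$charge[a]
    h <- g$atoms$hcount[a]
    deg_free <- sum(g$bonds$i[free_rows] == a | g$bonds$j[free_rows] == a)
    v <- .VALENCES[[el]]
    if (ch != 0L) v <- .default_valence(el, ch, 0L)
    # choose the admissible valence consistent with fixed part + free degree
    cand <- v[v - h - os_fixed[a] >= deg_free & v - h - os_fixed[a] <= 2L * deg_free]
    if (deg_free == 0L) {
      if (any(v == h + os_fixed[a])) return(0) else return(NA_real_)
    }
    if (!length(cand)) return(NA_real_)
    cand[1] - h - os_fixed[a]
  }, numeric(1))
  if (anyNA(res)) return(NULL)
  nf <- length(free_rows)
  if (nf == 0L) return(orders)
  fi <- g$bonds$i[free_rows]; fj <- g$bonds$j[free_rows]
  assign_rec <- function(k, res) {
    if (k > nf) return(if (all(res[unique(c(fi, fj))] == 0)) integer(0) else NULL)
    for (o in 1:2) {
      r2 <- res
      r2[fi[k]] <- r2[fi[k]] - o; r2[fj[k]] <- r2[fj[k]] - o
      if (r2[fi[k]] < 0 || r2[fj[k]] < 0) next
      # feasibility: remaining free degree must be able to absorb residual
      sol <- assign_rec(k + 1L, r2)
      if (!is.null(sol)) return(c(o, sol))
    }
    NULL
  }
  # feasibility pruning needs remaining free degrees; keep simple (graphs small)
  sol <- assign_rec(1L, res)
  if (is.null(sol)) return(NULL)
  orders[free_rows] <- sol[seq_len(nf)]
  orders
}
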