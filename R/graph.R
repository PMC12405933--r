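# Network structures: DAGs and partially directed graphs (PDAG/CPDAG).
#
# Internal convention: a graph over p named nodes is stored as an adjacency
# matrix `amat` with amat[i, j] = 1L when an edge i -> j is present.
# amat[i, j] = amat[j, i] = 1L encodes an undirected edge i - j.

#' Create a network structure
#'
#' Constructs a directed or partially directed graph over named nodes, the
#' common currency of all structure learners, the bootstrap consensus and the
#' inference engine. Directed two-cycles are disallowed; the directed part
#' must be acyclic.
#'
#' @param nodes Character vector of node names.
#' @param arcs Two-column character matrix (from, to) of directed arcs, or
#'   `NULL`.
#' @param undirected Two-column character matrix of undirected edges, or
#'   `NULL`.
#' @return An object of class `bn_graph` with elements `nodes` and `amat`.
#' @examples
#' g <- bn_graph(c("A", "B", "C"), arcs = rbind(c("A", "B"), c("B", "C")))
#' arcs(g)
#' @export
bn_graph <- function(nodes, arcs = NULL, undirected = NULL) {
  stopifnot(is.character(nodes), !anyDuplicated(nodes))
  p <- length(nodes)
  amat <- matrix(0L, p, p, dimnames = list(nodes, nodes))
  add_pairs <- function(m, sym) {
    if (is.null(m) || NROW(m) == 0L) return(invisible(NULL))
    m <- matrix(as.character(m), ncol = 2L)
    bad <- !(m %in% nodes)
    if (any(bad)) stop2("unknown node(s): %s", paste(unique(m[bad]), collapse = ", "))
    for (k in seq_len(nrow(m))) {
      if (m[k, 1] == m[k, 2]) stop2("self-loop at node '%s'", m[k, 1])
      amat[m[k, 1], m[k, 2]] <<- 1L
      if (sym) amat[m[k, 2], m[k, 1]] <<- 1L
    }
  }
  add_pairs(arcs, sym = FALSE)
  if (any(amat == 1L & t(amat) == 1L)) {
    stop2("arc set contains a 2-cycle (both directions listed as arcs)",
          class = "exacnet_cycle_error")
  }
  add_pairs(undirected, sym = TRUE)
  g <- structure(list(nodes = nodes, amat = amat), class = "bn_graph")
  if (!is_acyclic_amat(amat)) stop2("directed part of the graph is cyclic", class = "exacnet_cycle_error")
  g
}

graph_from_amat <- function(amat) {
  structure(list(nodes = rownames(amat), amat = amat), class = "bn_graph")
}

#' @export
print.bn_graph <- function(x, ...) {
  a <- arcs(x); u <- undirected_edges(x)
  cat(sprintf("Network structure: %d nodes, %d directed arc(s), %d undirected edge(s)\n",
              length(x$nodes), nrow(a), nrow(u)))
  if (nrow(a)) cat(paste0("  ", a[, 1], " -> ", a[, 2], collapse = "\n"), "\n")
  if (nrow(u)) cat(paste0("  ", u[, 1], " -- ", u[, 2], collapse = "\n"), "\n")
  invisible(x)
}

#' Directed arcs of a network structure
#' @param g A `bn_graph`.
#' @return Two-column character matrix (from, to).
#' @export
arcs <- function(g) {
  am <- g$amat
  dir <- which(am == 1L & t(am) == 0L, arr.ind = TRUE)
  out <- cbind(from = g$nodes[dir[, 1]], to = g$nodes[dir[, 2]])
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

#' Undirected edges of a network structure
#' @param g A `bn_graph`.
#' @return Two-column character matrix, each unordered pair listed once.
#' @export
undirected_edges <- function(g) {
  am <- g$amat
  und <- which(am == 1L & t(am) == 1L & upper.tri(am), arr.ind = TRUE)
  out <- cbind(from = g$nodes[und[, 1]], to = g$nodes[und[, 2]])
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

#' Parents of a node (directed arcs only)
#' @param g A `bn_graph`.
#' @param node Node name.
#' @return Character vector of parent names.
#' @export
parents <- function(g, node) {
  am <- g$amat
  g$nodes[am[, node] == 1L & am[node, ] == 0L]
}

is_dag <- function(g) nrow(undirected_edges(g)) == 0L && is_acyclic_amat(g$amat)

# acyclicity of the DIRECTED part (undirected edges ignored)
is_acyclic_amat <- function(amat) {
  d <- amat * (1L - t(amat)) # strip undirected edges
  p <- nrow(d)
  indeg <- colSums(d)
  active <- rep(TRUE, p)
  for (it in seq_len(p)) {
    roots <- which(active & indeg == 0L)
    if (!length(roots)) break
    for (r in roots) {
      indeg <- indeg - d[r, ]
      active[r] <- FALSE
    }
  }
  !any(active)
}

#' Topological order of a DAG
#' @param g A `bn_graph` with no undirected edges.
#' @return Character vector of node names, parents before children.
#' @export
topo_sort <- function(g) {
  if (nrow(undirected_edges(g)) > 0L) stop2("topological order requires a DAG")
  d <- g$amat
  indeg <- colSums(d)
  out <- character(0)
  active <- setNames(rep(TRUE, length(g$nodes)), g$nodes)
  while (any(active)) {
    roots <- names(active)[active & indeg == 0]
    # deterministic order within a level
    roots <- sort(roots)
    if (!length(roots)) stop2("graph is cyclic", class = "exacnet_cycle_error")
    out <- c(out, roots)
    for (r in roots) {
      indeg <- indeg - d[r, ]
      active[r] <- FALSE
    }
  }
  out
}

# TRUE if adding from -> to would create a directed cycle (directed part only)
would_cycle <- function(amat, from, to) {
  d <- amat * (1L - t(amat))
  # cycle iff `from` reachable from `to`
  reachable_from(d, to)[from]
}

reachable_from <- function(d, start) {
  p <- nrow(d)
  seen <- setNames(rep(FALSE, p), rownames(d))
  frontier <- start
  seen[start] <- TRUE
  while (length(frontier)) {
    nxt <- rownames(d)[colSums(d[frontier, , drop = FALSE]) > 0]
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  seen
}

# descendants of a node in a DAG (excluding the node itself)
descendants <- function(g, node) {
  seen <- reachable_from(g$amat * (1L - t(g$amat)), node)
  setdiff(names(seen)[seen], node)
}

# ---- Meek orientation rules ------------------------------------------------

adjacent <- function(am, i, j) am[i, j] == 1L || am[j, i] == 1L

# Apply Meek rules 1-4 to closure on an adjacency matrix. Orientation of an
# undirected edge i - j into i -> j simply clears am[j, i].
meek_closure <- function(am) {
  nodes <- rownames(am)
  repeat {
    changed <- FALSE
    und <- which(am == 1L & t(am) == 1L, arr.ind = TRUE)
    if (nrow(und)) {
      for (k in seq_len(nrow(und))) {
        b <- und[k, 1]; c <- und[k, 2] # consider orienting b -> c
        if (am[b, c] != 1L || am[c, b] != 1L) next # already oriented meanwhile
        orient <- FALSE
        dir_in_b <- which(am[, b] == 1L & am[b, ] == 0L) # a -> b
        # R1: a -> b, b - c, a and c nonadjacent  =>  b -> c
        for (a in dir_in_b) {
          if (!adjacent(am, a, c)) { orient <- TRUE; break }
        }
        # R2: b -> d -> c with b - c  =>  b -> c
        if (!orient) {
          d_out <- which(am[b, ] == 1L & am[, b] == 0L) # b -> d
          for (d in d_out) {
            if (am[d, c] == 1L && am[c, d] == 0L) { orient <- TRUE; break }
          }
        }
        # R3: b - c, b - d1, b - d2, d1 -> c, d2 -> c, d1,d2 nonadjacent => b -> c
        if (!orient) {
          nb_und <- which(am[b, ] == 1L & am[, b] == 1L)
          into_c <- nb_und[am[nb_und, c] == 1L & am[c, nb_und] == 0L]
          if (length(into_c) >= 2L) {
            for (i1 in seq_along(into_c)) {
              for (i2 in seq_along(into_c)) {
                if (i1 < i2 && !adjacent(am, into_c[i1], into_c[i2])) { orient <- TRUE }
              }
            }
          }
        }
        # R4: b - c; exists d -> e, e -> c with c,d... (b adjacent to both d, e;
        # c and d nonadjacent)  =>  b -> c
        if (!orient) {
          for (e in seq_along(nodes)) {
            if (am[e, c] == 1L && am[c, e] == 0L && adjacent(am, b, e)) { # e -> c
              d_in_e <- which(am[, e] == 1L & am[e, ] == 0L)              # d -> e
              for (d in d_in_e) {
                if (adjacent(am, b, d) && !adjacent(am, c, d)) { orient <- TRUE; break }
              }
            }
            if (orient) break
          }
        }
        if (orient && !would_cycle(am, b, c)) {
          am[c, b] <- 0L
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  am
}

#' Completed PDAG (CPDAG) of a DAG
#'
#' Returns the representative of the Markov equivalence class: the skeleton
#' with v-structures oriented and Meek rules applied to closure.
#'
#' @param g A `bn_graph` DAG.
#' @return A `bn_graph` in CPDAG form.
#' @export
cpdag_of <- function(g) {
  if (!is_dag(g)) stop2("cpdag_of() expects a DAG")
  d <- g$amat
  nodes <- g$nodes
  p <- length(nodes)
  # start from skeleton, all undirected
  am <- matrix(0L, p, p, dimnames = dimnames(d))
  am[d == 1L | t(d) == 1L] <- 1L
  # orient v-structures a -> c <- b with a, b nonadjacent
  for (ci in seq_len(p)) {
    pa <- which(d[, ci] == 1L)
    if (length(pa) >= 2L) {
      for (u in seq_along(pa)) for (v in seq_along(pa)) {
        if (u < v && d[pa[u], pa[v]] == 0L && d[pa[v], pa[u]] == 0L) {
          am[ci, pa[u]] <- 0L
          am[ci, pa[v]] <- 0L
        }
      }
    }
  }
  graph_from_amat(meek_closure(am))
}

#' Consistent extension of a PDAG to a DAG
#'
#' Orients every undirected edge without creating new v-structures or cycles
#' (Dor-Tarsi algorithm). Deterministic: candidate sink nodes are tried in
#' lexicographic order.
#'
#' @param g A `bn_graph` PDAG.
#' @param best_effort If `TRUE`, an inextensible PDAG does not error:
#'   the lexicographically first blocked undirected edge is oriented in a
#'   cycle-free direction and extension resumes (used for noisy averaged
#'   networks whose v-structure pattern admits no exact extension).
#' @return A `bn_graph` DAG with the same skeleton and v-structures
#'   (v-structures possibly augmented when `best_effort` kicks in).
#' @export
pdag_to_dag <- function(g, best_effort = FALSE) {
  am <- g$amat
  res <- am # orientations accumulate here
  nodes <- g$nodes
  active <- setNames(rep(TRUE, length(nodes)), nodes)
  while (any(active)) {
    act <- sort(names(active)[active])
    found <- NULL
    for (x in act) {
      others <- setdiff(act, x)
      # no directed edge x -> y among active nodes
      if (any(am[x, others] == 1L & am[others, x] == 0L)) next
      und_nb <- others[am[x, others] == 1L & am[others, x] == 1L]
      adj_x <- others[am[x, others] == 1L | am[others, x] == 1L]
      ok <- TRUE
      for (y in und_nb) {
        for (z in setdiff(adj_x, y)) {
          if (!adjacent(am, y, z)) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (ok) { found <- x; break }
    }
    if (is.null(found)) {
      if (!best_effort) {
        stop2("PDAG admits no consistent extension (offending nodes: %s)",
              paste(act, collapse = ", "), class = "exacnet_extension_error")
      }
      und <- which(am == 1L & t(am) == 1L, arr.ind = TRUE)
      und <- und[order(rownames(am)[und[, 1]], rownames(am)[und[, 2]]), , drop = FALSE]
      i <- und[1, 1]; j <- und[1, 2]
      if (would_cycle(res * (1L - t(res)), rownames(am)[i], rownames(am)[j])) {
        res[i, j] <- 0L; am[i, j] <- 0L
      } else {
        res[j, i] <- 0L; am[j, i] <- 0L
      }
      next
    }
    x <- found
    others <- setdiff(act, x)
    und_nb <- others[am[x, others] == 1L & am[others, x] == 1L]
    for (y in und_nb) res[x, y] <- 0L # orient y -> x
    # remove x from the active subgraph
    am[x, ] <- 0L; am[, x] <- 0L
    active[x] <- FALSE
  }
  out <- graph_from_amat(res)
  if (!is_dag(out)) stop2("internal error: extension produced a non-DAG")
  out
}

#' Structural Hamming distance between two partially directed graphs
#'
#' Counts node pairs whose edge status differs: a missing or extra adjacency
#' counts 1, as does any orientation mismatch (including directed vs
#' undirected).
#'
#' @param g1,g2 `bn_graph` objects over the same node set.
#' @return Integer distance.
#' @export
shd <- function(g1, g2) {
  stopifnot(setequal(g1$nodes, g2$nodes))
  a1 <- g1$amat[g1$nodes, g1$nodes]
  a2 <- g2$amat[g1$nodes, g1$nodes]
  d <- 0L
  p <- length(g1$nodes)
  for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
    e1 <- c(a1[i, j], a1[j, i])
    e2 <- c(a2[i, j], a2[j, i])
    if (!all(e1 == e2)) d <- d + 1L
  }
  d
}

# all DAG adjacency structures over given nodes (exhaustive; <= 5 nodes)
all_dags <- function(nodes) {
  p <- length(nodes)
  pairs <- t(combn(p, 2L))
  npairs <- nrow(pairs)
  out <- list()
  # each unordered pair has 3 states: none, i->j, j->i
  states <- rep(0L, npairs)
  repeat {
    am <- matrix(0L, p, p, dimnames = list(nodes, nodes))
    for (k in seq_len(npairs)) {
      if (states[k] == 1L) am[pairs[k, 1], pairs[k, 2]] <- 1L
      if (states[k] == 2L) am[pairs[k, 2], pairs[k, 1]] <- 1L
    }
    if (is_acyclic_amat(am)) out[[length(out) + 1L]] <- am
    # increment base-3 counter
    k <- 1L
    while (k <= npairs) {
      states[k] <- states[k] + 1L
      if (states[k] <= 2L) break
      states[k] <- 0L
      k <- k + 1L
    }
    if (k > npairs) break
  }
  out
}
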