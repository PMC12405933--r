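# Constraint-based structure learning: the order-independent (stable) variant
# of the Peter-Clark algorithm.

#' PC-stable structure learning
#'
#' Learns a CPDAG by the stable-skeleton PC algorithm: at each depth the
#' neighbour sets are frozen before any edge removal, making the skeleton
#' independent of column order. Separating sets are recorded, unshielded
#' colliders are oriented as v-structures, and Meek rules are applied to
#' closure. Pairs blacklisted in both directions start disconnected;
#' whitelisted edges are never removed and, when whitelisted in one
#' direction only, are oriented accordingly.
#'
#' @param data Data frame of factors.
#' @param alpha Significance level for the conditional independence test.
#' @param whitelist,blacklist Two-column (from, to) arc matrices.
#' @param test Conditional independence test, see [g2_test()].
#' @param max_sx Maximum conditioning set size.
#' @return A `bn_graph` in CPDAG/PDAG form with attribute `"ntests"`.
#' @export
pc_stable <- function(data, alpha = 0.05, whitelist = NULL, blacklist = NULL,
                      test = "g2", max_sx = Inf) {
  stopifnot(alpha > 0, alpha < 1)
  dd <- as_discrete_data(data)
  nodes <- dd$nodes
  p <- length(nodes)
  cm <- constraint_masks(nodes, whitelist, blacklist)
  protected <- cm$wl | t(cm$wl) # adjacency may not be removed
  adj <- matrix(TRUE, p, p, dimnames = list(nodes, nodes))
  diag(adj) <- FALSE
  adj[cm$bl & t(cm$bl)] <- FALSE
  adj <- adj & t(adj)
  sepset <- new.env(parent = emptyenv())
  sep_key <- function(x, y) paste(sort(c(x, y)), collapse = "|")
  use_g2 <- identical(test, "g2")
  tcache <- dd$cache %||% new.env(parent = emptyenv())
  ntests <- 0L

  depth <- 0L
  repeat {
    frozen <- adj # stable variant: neighbour sets fixed for this depth
    any_testable <- FALSE
    for (xi in seq_len(p)) for (yi in seq_len(p)) {
      if (xi == yi || !adj[xi, yi]) next
      x <- nodes[xi]; y <- nodes[yi]
      if (protected[x, y]) next
      nb <- nodes[frozen[xi, ] & seq_len(p) != yi]
      if (length(nb) < depth) next
      any_testable <- TRUE
      subsets <- if (depth == 0L) list(character(0)) else
        utils::combn(nb, depth, simplify = FALSE)
      for (S in subsets) {
        ntests <- ntests + 1L
        pv <- if (use_g2) ci_pvalue(dd, x, y, S, tcache) else g2_test(x, y, S, dd, test = test)$p_value
        if (pv > alpha) {
          adj[xi, yi] <- adj[yi, xi] <- FALSE
          sepset[[sep_key(x, y)]] <- S
          break
        }
      }
    }
    depth <- depth + 1L
    if (!any_testable || depth > max_sx) break
  }

  # orient v-structures x -> z <- y (x, y nonadjacent, z not in sepset(x, y))
  am <- matrix(0L, p, p, dimnames = list(nodes, nodes))
  am[adj] <- 1L
  for (zi in seq_len(p)) {
    nbz <- which(adj[zi, ])
    if (length(nbz) < 2L) next
    for (a in seq_along(nbz)) for (b in seq_along(nbz)) {
      if (a >= b) next
      xi <- nbz[a]; yi <- nbz[b]
      if (adj[xi, yi]) next
      S <- sepset[[sep_key(nodes[xi], nodes[yi])]]
      if (!is.null(S) && !(nodes[zi] %in% S)) {
        x <- nodes[xi]; y <- nodes[yi]; z <- nodes[zi]
        # orient into the collider unless blacklisted, already reversed by a
        # conflicting v-structure, or cycle-inducing (conflicts are skipped)
        for (par in c(x, y)) {
          if (!cm$bl[par, z] && am[par, z] == 1L && am[z, par] == 1L) {
            am2 <- am; am2[z, par] <- 0L
            if (is_acyclic_amat(am2)) am <- am2
          }
        }
      }
    }
  }
  # whitelist orientations
  wpairs <- which(cm$wl, arr.ind = TRUE)
  for (k in seq_len(nrow(wpairs))) {
    x <- nodes[wpairs[k, 1]]; y <- nodes[wpairs[k, 2]]
    am[x, y] <- 1L
    am[y, x] <- 0L
  }
  if (!is_acyclic_amat(am)) {
    stop2("constraints force a cyclic orientation", class = "exacnet_cycle_error")
  }
  g <- graph_from_amat(meek_closure(am))
  attr(g, "ntests") <- ntests
  g
}
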