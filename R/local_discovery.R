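# Local neighbourhood discovery: Grow-Shrink Markov blankets and the
# Max-Min / semi-interleaved HITON parents-and-children algorithms.

# smallest p-value retained: association of x with target t given subsets of
# `cond_pool` up to size max_sx; returns the MAXIMUM p-value over subsets
# (the "min association"), which is what backward pruning and the max-min
# heuristic need.
max_pvalue_over_subsets <- function(dd, x, t, cond_pool, alpha, max_sx, cache = NULL) {
  worst <- 0
  for (d in 0:min(length(cond_pool), max_sx)) {
    subsets <- if (d == 0L) list(character(0)) else utils::combn(cond_pool, d, simplify = FALSE)
    for (S in subsets) {
      pv <- ci_pvalue(dd, x, t, S, cache)
      if (pv > worst) worst <- pv
      if (worst > alpha) return(worst) # independent given some subset: done
    }
  }
  worst
}

gs_blanket <- function(dd, target, alpha, max_sx, cache = NULL) {
  vars <- setdiff(dd$nodes, target)
  mb <- character(0)
  # grow phase
  repeat {
    added <- FALSE
    for (x in setdiff(vars, mb)) {
      if (ci_pvalue(dd, x, target, mb, cache) <= alpha) {
        mb <- c(mb, x)
        added <- TRUE
      }
    }
    if (!added) break
  }
  # shrink phase
  repeat {
    dropped <- FALSE
    for (x in mb) {
      if (ci_pvalue(dd, x, target, setdiff(mb, x), cache) > alpha) {
        mb <- setdiff(mb, x)
        dropped <- TRUE
        break
      }
    }
    if (!dropped) break
  }
  sort(mb)
}

mmpc_set <- function(dd, target, alpha, max_sx, cache = NULL) {
  cache <- cache %||% new.env(parent = emptyenv())
  vars <- setdiff(dd$nodes, target)
  cpc <- character(0)
  repeat {
    rest <- setdiff(vars, cpc)
    if (!length(rest)) break
    # max-min heuristic: candidate minimizing its maximum p-value over
    # subsets of the current CPC (memoized: rounds revisit the same tests)
    minp <- vapply(rest, function(x)
      max_pvalue_over_subsets(dd, x, target, cpc, alpha, max_sx, cache), 1.0)
    best <- which.min(minp)
    if (minp[best] > alpha) break
    cpc <- c(cpc, rest[best])
  }
  backward_prune(dd, target, cpc, alpha, max_sx, cache)
}

si_hiton_pc_set <- function(dd, target, alpha, max_sx, cache = NULL) {
  cache <- cache %||% new.env(parent = emptyenv())
  vars <- setdiff(dd$nodes, target)
  marg <- vapply(vars, function(x) ci_pvalue(dd, x, target, character(0), cache), 1.0)
  queue <- vars[marg <= alpha][order(marg[marg <= alpha])]
  cpc <- character(0)
  for (x in queue) {
    # semi-interleaved: only the incoming candidate is tested at insertion,
    # against subsets of the current tentative set
    if (max_pvalue_over_subsets(dd, x, target, cpc, alpha, max_sx, cache) <= alpha) {
      cpc <- c(cpc, x)
    }
  }
  backward_prune(dd, target, cpc, alpha, max_sx, cache)
}

backward_prune <- function(dd, target, cpc, alpha, max_sx, test) {
  repeat {
    dropped <- FALSE
    for (x in cpc) {
      if (max_pvalue_over_subsets(dd, x, target, setdiff(cpc, x), alpha, max_sx, test) > alpha) {
        cpc <- setdiff(cpc, x)
        dropped <- TRUE
        break
      }
    }
    if (!dropped) break
  }
  sort(cpc)
}

#' Local Markov blanket / parents-and-children discovery
#'
#' Returns the local neighbourhood of a target variable: the Markov blanket
#' via Grow-Shrink, or the parents-and-children set via the Max-Min
#' heuristic with backward pruning (MMPC) or semi-interleaved HITON-PC.
#' All strategies apply the symmetry correction: a variable X is kept in the
#' neighbourhood of the target T only if T is in turn recovered in the
#' neighbourhood of X.
#'
#' @param data Data frame of factors.
#' @param target Target variable name.
#' @param strategy `"grow_shrink"`, `"mmpc"` or `"si_hiton_pc"`.
#' @param alpha Significance level.
#' @param max_sx Maximum conditioning set size for the subset searches.
#' @param symmetry Apply the AND symmetry correction (default `TRUE`).
#' @param test Conditional independence test, see [g2_test()].
#' @return Sorted character vector of neighbourhood members.
#' @export
markov_blanket_local <- function(data, target,
                                 strategy = c("grow_shrink", "mmpc", "si_hiton_pc"),
                                 alpha = 0.05, max_sx = 3L, symmetry = TRUE,
                                 test = "g2") {
  strategy <- match.arg(strategy)
  dd <- as_discrete_data(data)
  if (!target %in% dd$nodes) stop2("target '%s' not in data", target)
  fn <- switch(strategy, grow_shrink = gs_blanket, mmpc = mmpc_set,
               si_hiton_pc = si_hiton_pc_set)
  cache <- dd$cache %||% new.env(parent = emptyenv())
  set <- fn(dd, target, alpha, max_sx, cache)
  if (symmetry && length(set)) {
    keep <- vapply(set, function(x) target %in% fn(dd, x, alpha, max_sx, cache), TRUE)
    set <- set[keep]
  }
  sort(set)
}

# symmetric (AND-rule) skeleton from per-node local sets; returns bn_graph
# with undirected edges only
local_skeleton <- function(dd, strategy, alpha, max_sx) {
  fn <- switch(strategy, grow_shrink = gs_blanket, mmpc = mmpc_set,
               si_hiton_pc = si_hiton_pc_set)
  cache <- dd$cache %||% new.env(parent = emptyenv())
  sets <- lapply(dd$nodes, function(t) fn(dd, t, alpha, max_sx, cache))
  names(sets) <- dd$nodes
  edges <- matrix(character(0), ncol = 2L)
  for (x in dd$nodes) for (y in sets[[x]]) {
    if (x < y && x %in% sets[[y]]) edges <- rbind(edges, c(x, y))
  }
  bn_graph(dd$nodes, undirected = edges)
}

#' Two-phase restricted maximization (RSMAX2)
#'
#' Phase 1 builds a candidate skeleton as the union of symmetry-corrected
#' local neighbourhoods (Grow-Shrink, MMPC or SI-HITON-PC); phase 2 runs
#' hill climbing restricted to candidate adjacencies. Whitelisted arcs are
#' added to the candidate skeleton; blacklists are honoured in both phases.
#'
#' @param data Data frame of factors.
#' @param restrict_strategy Local discovery strategy for phase 1.
#' @param maximize_score Score for the hill-climbing phase.
#' @param alpha Significance level for phase 1.
#' @param max_sx Maximum conditioning set size for phase 1.
#' @param whitelist,blacklist Two-column (from, to) arc matrices.
#' @param tabu_length Passed to [hill_climb()] for phase 2.
#' @param ess BDeu equivalent sample size.
#' @return A `bn_graph` DAG with attributes `"score"` and `"skeleton"`.
#' @export
rsmax2 <- function(data, restrict_strategy = c("si_hiton_pc", "mmpc", "grow_shrink"),
                   maximize_score = c("bic", "bdeu"), alpha = 0.05, max_sx = 3L,
                   whitelist = NULL, blacklist = NULL, tabu_length = 0, ess = 1) {
  restrict_strategy <- match.arg(restrict_strategy)
  maximize_score <- match.arg(maximize_score)
  dd <- as_discrete_data(data)
  skel <- local_skeleton(dd, restrict_strategy, alpha, max_sx)
  allowed <- skel$amat == 1L
  wm <- as_arc_matrix(whitelist)
  for (k in seq_len(nrow(wm))) {
    allowed[wm[k, 1], wm[k, 2]] <- TRUE
    allowed[wm[k, 2], wm[k, 1]] <- TRUE
  }
  # blacklist every arc outside the candidate skeleton
  nodes <- dd$nodes
  bl2 <- which(!allowed & row(allowed) != col(allowed), arr.ind = TRUE)
  bl <- cbind(nodes[bl2[, 1]], nodes[bl2[, 2]])
  bm <- as_arc_matrix(blacklist)
  if (nrow(bm)) bl <- rbind(bl, bm)
  g <- hill_climb(data, score = maximize_score, whitelist = whitelist,
                  blacklist = bl, ess = ess, tabu_length = tabu_length)
  attr(g, "skeleton") <- skel
  g
}
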