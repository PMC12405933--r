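# Score-based structure learning: greedy hill climbing and tabu search.

# normalize user constraint input to a 2-column character matrix
as_arc_matrix <- function(x) {
  if (is.null(x) || NROW(x) == 0L) return(matrix(character(0), ncol = 2L))
  m <- matrix(as.character(x), ncol = 2L)
  colnames(m) <- c("from", "to")
  m
}

constraint_masks <- function(nodes, whitelist, blacklist) {
  p <- length(nodes)
  wl <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  bl <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  wm <- as_arc_matrix(whitelist); bm <- as_arc_matrix(blacklist)
  for (k in seq_len(nrow(wm))) wl[wm[k, 1], wm[k, 2]] <- TRUE
  for (k in seq_len(nrow(bm))) bl[bm[k, 1], bm[k, 2]] <- TRUE
  if (any(wl & t(wl))) {
    stop2("whitelist forces a cycle", class = "exacnet_cycle_error")
  }
  if (any(wl & bl)) stop2("whitelist and blacklist overlap")
  # a whitelisted arc forbids its reverse
  bl[t(wl)] <- TRUE
  list(wl = wl, bl = bl)
}

#' Hill-climbing (and tabu) search for a discrete Bayesian network
#'
#' Greedy search over single-arc additions, deletions and reversals,
#' maximizing a decomposable score. With `tabu_length > 0` the search becomes
#' tabu search: the best non-tabu neighbour is accepted even when it does not
#' improve, recently undone moves are excluded, and the best structure seen
#' is returned. Acyclicity is enforced at every move; whitelisted arcs are
#' always present and blacklisted arcs never appear. Ties between equal-score
#' moves are broken lexicographically by (operation, from, to) so results are
#' deterministic.
#'
#' @param data Data frame of factors.
#' @param score `"bic"` (default) or `"bdeu"`.
#' @param restarts Number of random restarts (each perturbs the local optimum
#'   and re-runs the search, keeping the best-scoring result).
#' @param tabu_length Length of the move-exclusion list; 0 gives plain hill
#'   climbing.
#' @param whitelist,blacklist Two-column (from, to) arc matrices.
#' @param seed Seed for restart perturbations (unused when `restarts = 0`).
#' @param ess BDeu equivalent sample size.
#' @param max_iter Safety cap on search iterations.
#' @return A `bn_graph` DAG with attribute `"score"`.
#' @export
hill_climb <- function(data, score = c("bic", "bdeu"), restarts = 0, tabu_length = 0,
                       whitelist = NULL, blacklist = NULL, seed = NULL, ess = 1,
                       max_iter = 500L) {
  score <- match.arg(score)
  dd <- as_discrete_data(data)
  nodes <- dd$nodes
  cm <- constraint_masks(nodes, whitelist, blacklist)
  start <- matrix(0L, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  start[cm$wl] <- 1L
  if (!is_acyclic_amat(start)) {
    stop2("whitelist forces a cycle", class = "exacnet_cycle_error")
  }
  run1 <- function(init_amat) {
    hc_engine(dd, init_amat, score, ess, tabu_length, cm$wl, cm$bl, max_iter)
  }
  best <- run1(start)
  if (restarts > 0) {
    rng <- if (is.null(seed)) stop2("`seed` is required when restarts > 0") else seed
    for (r in seq_len(restarts)) {
      pert <- withr::with_seed(derive_seed(rng, paste0("hc_restart", r)),
                               perturb_amat(best$amat, cm$wl, cm$bl))
      cand <- run1(pert)
      if (cand$score > best$score + 1e-10) best <- cand
    }
  }
  g <- graph_from_amat(best$amat)
  attr(g, "score") <- best$score
  g
}

perturb_amat <- function(amat, wl, bl, n_moves = 4L) {
  # mixed random additions, deletions and reversals so restarts explore a
  # genuinely different basin
  nodes <- rownames(amat)
  for (k in seq_len(n_moves)) {
    op <- sample(c("add", "delete", "reverse"), 1L)
    if (op == "add") {
      cand <- which(amat == 0L & t(amat) == 0L & !bl & row(amat) != col(amat))
      if (!length(cand)) next
      pick <- cand[sample.int(length(cand), 1L)]
      i <- row(amat)[pick]; j <- col(amat)[pick]
      if (!would_cycle(amat, nodes[i], nodes[j])) amat[i, j] <- 1L
    } else {
      cand <- which(amat == 1L & !wl)
      if (!length(cand)) next
      pick <- cand[sample.int(length(cand), 1L)]
      i <- row(amat)[pick]; j <- col(amat)[pick]
      amat[i, j] <- 0L
      if (op == "reverse" && !bl[j, i] && !would_cycle(amat, nodes[j], nodes[i])) {
        amat[j, i] <- 1L
      }
    }
  }
  amat
}

hc_engine <- function(dd, amat, score, ess, tabu_length, wl, bl, max_iter) {
  nodes <- dd$nodes
  p <- length(nodes)
  pa_of <- function(am, y) nodes[am[, y] == 1L]
  fs <- vapply(nodes, function(y) family_score_dd(dd, y, pa_of(amat, y), score, ess), 1.0)
  d_add <- matrix(NA_real_, p, p, dimnames = list(nodes, nodes))
  d_del <- matrix(NA_real_, p, p, dimnames = list(nodes, nodes))
  refresh_target <- function(y) {
    pay <- pa_of(amat, y)
    for (x in nodes) {
      if (x == y) next
      if (amat[x, y] == 1L) {
        d_del[x, y] <<- family_score_dd(dd, y, setdiff(pay, x), score, ess) - fs[y]
        d_add[x, y] <<- NA_real_
      } else {
        d_add[x, y] <<- family_score_dd(dd, y, c(pay, x), score, ess) - fs[y]
        d_del[x, y] <<- NA_real_
      }
    }
  }
  for (y in nodes) refresh_target(y)

  tabu <- list() # recent moves (op, from, to) that may not be undone
  is_tabu <- function(op, x, y) {
    any(vapply(tabu, function(t) identical(t, c(op, x, y)), TRUE))
  }
  push_tabu <- function(op, x, y) {
    if (tabu_length > 0) {
      tabu[[length(tabu) + 1L]] <<- c(op, x, y)
      if (length(tabu) > tabu_length) tabu <<- tabu[-1L]
    }
  }

  cur_total <- sum(fs)
  best_amat <- amat
  best_total <- cur_total
  stall <- 0L

  for (it in seq_len(max_iter)) {
    # transitive closure of the current DAG (reach[i, j]: path i -> j)
    reach <- amat > 0L
    for (k in seq_len(p)) {
      reach <- reach | (reach[, k] %o% reach[k, ])
    }
    no_edge <- amat == 0L & t(amat) == 0L & row(amat) != col(amat)
    can_add <- no_edge & !bl & !t(reach) # t(reach)[x, y] = path y -> x
    has_arc <- amat == 1L
    can_del <- has_arc & !wl
    can_rev <- has_arc & !wl & !t(bl)
    ops <- c(rep("add", sum(can_add)), rep("delete", sum(can_del)),
             rep("reverse", sum(can_rev)))
    ia <- which(can_add); id <- which(can_del); ir <- which(can_rev)
    xs <- nodes[(c(ia, id, ir) - 1L) %% p + 1L]
    ys <- nodes[(c(ia, id, ir) - 1L) %/% p + 1L]
    deltas <- c(d_add[ia], d_del[id], d_del[ir] + d_add[cbind(ys[ops == "reverse"],
                                                              xs[ops == "reverse"])])
    if (!length(deltas)) break
    # score-equivalent moves differ only by float noise; quantize so the
    # documented lexicographic tie-break actually governs ties
    ordx <- order(-round(deltas, 6), ops, xs, ys)
    mv <- NULL
    for (ci in ordx) {
      x <- xs[ci]; y <- ys[ci]; op <- ops[ci]
      if (is_tabu(op, x, y)) next
      if (op == "reverse") {
        am2 <- amat; am2[x, y] <- 0L
        if (would_cycle(am2, y, x)) next
      }
      mv <- list(op = op, x = x, y = y, delta = deltas[ci])
      break
    }
    if (is.null(mv)) break
    improving <- mv$delta > 1e-10
    if (tabu_length == 0 && !improving) break

    affected <- mv$y
    if (mv$op == "add") {
      amat[mv$x, mv$y] <- 1L
      push_tabu("delete", mv$x, mv$y)
    } else if (mv$op == "delete") {
      amat[mv$x, mv$y] <- 0L
      push_tabu("add", mv$x, mv$y)
    } else {
      amat[mv$x, mv$y] <- 0L
      amat[mv$y, mv$x] <- 1L
      affected <- c(mv$x, mv$y)
      push_tabu("reverse", mv$y, mv$x)
    }
    for (y in affected) {
      fs[y] <- family_score_dd(dd, y, pa_of(amat, y), score, ess)
    }
    for (y in affected) refresh_target(y)
    # reversals invalidate add-deltas into the two endpoints only; other
    # targets' parent sets are untouched, so their cached deltas stay valid
    cur_total <- sum(fs)
    if (cur_total > best_total + 1e-10) {
      best_total <- cur_total
      best_amat <- amat
      stall <- 0L
    } else if (tabu_length > 0) {
      # tabu exploration budget: iterations since the best structure improved
      stall <- stall + 1L
      if (stall >= max(tabu_length, 10L)) break
    }
  }
  list(amat = best_amat, score = best_total)
}

#' Exhaustive search over all DAGs (small instances)
#'
#' Enumerates every DAG over the data's columns and returns the one with the
#' best decomposable score. Intended as an independent optimality reference
#' for the greedy learners; limited to 5 nodes.
#'
#' @inheritParams hill_climb
#' @return A `bn_graph` DAG with attribute `"score"`.
#' @export
exhaustive_dag_search <- function(data, score = c("bic", "bdeu"), ess = 1) {
  score <- match.arg(score)
  dd <- as_discrete_data(data)
  if (length(dd$nodes) > 5L) stop2("exhaustive search is limited to 5 nodes")
  cache <- new.env(parent = emptyenv())
  fam <- function(y, pa) {
    key <- paste(y, paste(sort(pa), collapse = ","), sep = "|")
    if (is.null(cache[[key]])) cache[[key]] <- family_score_dd(dd, y, pa, score, ess)
    cache[[key]]
  }
  best <- NULL; best_s <- -Inf
  for (am in all_dags(dd$nodes)) {
    s <- sum(vapply(dd$nodes, function(y) fam(y, dd$nodes[am[, y] == 1L]), 1.0))
    if (s > best_s) { best_s <- s; best <- am }
  }
  g <- graph_from_amat(best)
  attr(g, "score") <- best_s
  g
}
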