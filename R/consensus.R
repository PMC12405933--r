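# Bootstrap, multi-algorithm consensus structure learning with expert
# constraints: the step that produces the final network.

learner_registry <- function() {
  list(
    hc          = function(d, wl, bl) hill_climb(d, whitelist = wl, blacklist = bl),
    tabu        = function(d, wl, bl) hill_climb(d, whitelist = wl, blacklist = bl, tabu_length = 10),
    pc_stable   = function(d, wl, bl) pc_stable(d, whitelist = wl, blacklist = bl),
    gs          = function(d, wl, bl) local_skeleton(as_discrete_data(d), "grow_shrink", 0.05, 3L),
    mmpc        = function(d, wl, bl) local_skeleton(as_discrete_data(d), "mmpc", 0.05, 3L),
    si_hiton_pc = function(d, wl, bl) local_skeleton(as_discrete_data(d), "si_hiton_pc", 0.05, 3L),
    rsmax2_gs   = function(d, wl, bl) rsmax2(d, "grow_shrink", whitelist = wl, blacklist = bl),
    rsmax2_mmpc = function(d, wl, bl) rsmax2(d, "mmpc", whitelist = wl, blacklist = bl),
    rsmax2      = function(d, wl, bl) rsmax2(d, "si_hiton_pc", whitelist = wl, blacklist = bl)
  )
}

#' Bootstrap arc strengths across resamples and algorithms
#'
#' For each of `B` bootstrap resamples (drawn with replacement, size
#' `m_fraction * n`) every requested algorithm learns a structure under the
#' given constraints. All `B x length(algorithms)` learned graphs are pooled
#' with equal weight into per-pair adjacency frequencies and per-direction
#' frequencies; undirected edges (from CPDAG or skeleton-only learners)
#' contribute one half to each direction. Learner failures on a replicate
#' are logged and skipped; more than 5\% failures aborts.
#'
#' @param data Data frame of factors.
#' @param algorithms Character vector naming learners: any of `"hc"`,
#'   `"tabu"`, `"pc_stable"`, `"gs"`, `"mmpc"`, `"si_hiton_pc"`,
#'   `"rsmax2"`, `"rsmax2_gs"`, `"rsmax2_mmpc"`.
#' @param B Number of bootstrap replicates (default 1000).
#' @param m_fraction Resample size as a fraction of `n` (default 1).
#' @param constraints An `expert_constraints()` object or `NULL`.
#' @param seed Integer seed; replicate resamples derive from it.
#' @return An `arc_strengths` data frame: columns `from`, `to` (ordered
#'   pairs, each unordered pair appearing twice), `adjacency_frequency`,
#'   `direction_frequency`. Attributes carry the per-algorithm tables and
#'   the failure log.
#' @export
bootstrap_strengths <- function(data, algorithms = c("hc", "tabu", "pc_stable", "rsmax2_gs", "rsmax2_mmpc"),
                                B = 1000L, m_fraction = 1, constraints = NULL, seed = 1L) {
  stopifnot(B >= 1, m_fraction > 0, m_fraction <= 1)
  reg <- learner_registry()
  bad <- setdiff(algorithms, names(reg))
  if (length(bad)) stop2("unknown algorithm(s): %s", paste(bad, collapse = ", "))
  dd0 <- as_discrete_data(data)
  nodes <- dd0$nodes
  p <- length(nodes)
  wl <- if (is.null(constraints)) NULL else constraints$whitelist
  bl <- if (is.null(constraints)) NULL else constraints$blacklist
  m <- max(1L, round(m_fraction * dd0$n))

  dir_count <- matrix(0, p, p, dimnames = list(nodes, nodes)) # half-weighted
  adj_count <- matrix(0, p, p, dimnames = list(nodes, nodes))
  per_algo <- lapply(algorithms, function(a) list(dir = dir_count, adj = adj_count, n = 0))
  names(per_algo) <- algorithms
  failures <- list()
  total <- 0L

  dc <- compress_ddata(dd0)
  for (b in seq_len(B)) {
    db <- withr::with_seed(derive_seed(seed, paste0("boot", b)),
                           resample_ddata(dc, m))
    for (a in algorithms) {
      total <- total + 1L
      g <- tryCatch(reg[[a]](db, wl, bl), error = function(e) e)
      if (inherits(g, "error")) {
        failures[[length(failures) + 1L]] <- list(replicate = b, algorithm = a,
                                                  message = conditionMessage(g))
        next
      }
      # DAG learners are reduced to their equivalence class before counting:
      # only compelled arcs carry direction, reversible ones contribute 1/2
      if (is_dag(g) && nrow(arcs(g))) g <- cpdag_of(g)
      am <- g$amat[nodes, nodes]
      und <- (am == 1L) & (t(am) == 1L)
      dirm <- (am == 1L) & (t(am) == 0L)
      contrib_dir <- dirm + und / 2
      contrib_adj <- (am | t(am)) * 1
      dir_count <- dir_count + contrib_dir
      adj_count <- adj_count + contrib_adj
      per_algo[[a]]$dir <- per_algo[[a]]$dir + contrib_dir
      per_algo[[a]]$adj <- per_algo[[a]]$adj + contrib_adj
      per_algo[[a]]$n <- per_algo[[a]]$n + 1
    }
  }
  nfail <- length(failures)
  if (nfail > 0.05 * total) {
    stop2("%d of %d learner runs failed (> 5%%); first failure [%s, replicate %d]: %s",
          nfail, total, failures[[1]]$algorithm, failures[[1]]$replicate,
          failures[[1]]$message)
  }
  ngraphs <- total - nfail
  out <- strengths_table(nodes, adj_count / ngraphs, dir_count, adj_count)
  attr(out, "per_algorithm") <- lapply(per_algo, function(x)
    strengths_table(nodes, x$adj / max(x$n, 1), x$dir, x$adj))
  attr(out, "failures") <- failures
  attr(out, "ngraphs") <- ngraphs
  class(out) <- c("arc_strengths", class(out))
  out
}

strengths_table <- function(nodes, adj_freq, dir_count, adj_count) {
  pairs <- which(upper.tri(adj_freq), arr.ind = TRUE)
  rows <- list()
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    af <- adj_freq[i, j]
    dfwd <- if (adj_count[i, j] > 0) dir_count[i, j] / adj_count[i, j] else 0.5
    rows[[length(rows) + 1L]] <- data.frame(from = nodes[i], to = nodes[j],
                                            adjacency_frequency = af,
                                            direction_frequency = dfwd)
    rows[[length(rows) + 1L]] <- data.frame(from = nodes[j], to = nodes[i],
                                            adjacency_frequency = af,
                                            direction_frequency = 1 - dfwd)
  }
  out <- do.call(rbind, rows)
  attr(out, "nodes") <- nodes
  out
}

#' Model-averaged network from arc strengths
#'
#' Keeps every unordered pair whose adjacency frequency reaches `threshold`
#' and orients it in the direction supported by more than
#' `0.5 + direction_margin` of the replicates containing it; ties (or
#' margins not reached) stay undirected.
#'
#' @param strengths An `arc_strengths` table from [bootstrap_strengths()].
#' @param threshold Adjacency frequency cutoff in (0, 1], default 0.75.
#' @param direction_margin Extra majority required to orient (default 0).
#' @return A `bn_graph` PDAG.
#' @export
averaged_network <- function(strengths, threshold = 0.75, direction_margin = 0) {
  stopifnot(threshold > 0, threshold <= 1)
  nodes <- attr(strengths, "nodes")
  keep <- list()
  seen <- character(0)
  for (k in seq_len(nrow(strengths))) {
    r <- strengths[k, ]
    key <- paste(sort(c(r$from, r$to)), collapse = "|")
    if (key %in% seen) next
    seen <- c(seen, key)
    if (r$adjacency_frequency < threshold) next
    if (r$direction_frequency > 0.5 + direction_margin) {
      keep[[length(keep) + 1L]] <- list(from = r$from, to = r$to,
                                        dir = TRUE, df = r$direction_frequency)
    } else if (1 - r$direction_frequency > 0.5 + direction_margin) {
      keep[[length(keep) + 1L]] <- list(from = r$to, to = r$from,
                                        dir = TRUE, df = 1 - r$direction_frequency)
    } else {
      keep[[length(keep) + 1L]] <- list(from = r$from, to = r$to,
                                        dir = FALSE, df = 0.5)
    }
  }
  # majority directions pooled over replicates need not be jointly acyclic:
  # orient in decreasing direction-frequency order and demote any
  # cycle-inducing orientation to an undirected edge (deterministic)
  am <- matrix(0L, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  ord <- order(-vapply(keep, `[[`, 1.0, "df"),
               vapply(keep, `[[`, "", "from"), vapply(keep, `[[`, "", "to"))
  for (e in keep[ord]) {
    if (e$dir && !would_cycle(am, e$from, e$to)) {
      am[e$from, e$to] <- 1L
    } else {
      am[e$from, e$to] <- 1L
      am[e$to, e$from] <- 1L
    }
  }
  graph_from_amat(am)
}

#' Expert knowledge constraints
#'
#' Whitelists arcs that must appear (with direction) and blacklists arcs or
#' directions that are clinically implausible. The whitelist must be acyclic
#' and disjoint from the blacklist.
#'
#' @param whitelist,blacklist Two-column (from, to) arc matrices or `NULL`.
#' @return An `expert_constraints` object.
#' @export
expert_constraints <- function(whitelist = NULL, blacklist = NULL) {
  wm <- as_arc_matrix(whitelist); bm <- as_arc_matrix(blacklist)
  if (nrow(wm)) {
    keys_w <- paste(wm[, 1], wm[, 2])
    if (nrow(bm) && any(keys_w %in% paste(bm[, 1], bm[, 2])))
      stop2("whitelist and blacklist overlap")
    g <- bn_graph(unique(c(wm)), arcs = wm) # errors if cyclic
  }
  structure(list(whitelist = wm, blacklist = bm), class = "expert_constraints")
}

#' Apply expert constraints to a learned network
#'
#' Removes blacklisted arcs (a directed blacklist entry also reverts a
#' matching directed arc of an undirected-pair orientation), adds and orients
#' whitelisted arcs, and re-checks that the directed part remains extendable
#' to a DAG.
#'
#' @param network A `bn_graph`.
#' @param constraints An `expert_constraints` object.
#' @return A `bn_graph`.
#' @export
apply_expert_constraints <- function(network, constraints) {
  stopifnot(inherits(constraints, "expert_constraints"))
  am <- network$amat
  nodes <- network$nodes
  bm <- constraints$blacklist
  for (k in seq_len(nrow(bm))) {
    x <- bm[k, 1]; y <- bm[k, 2]
    if (!all(c(x, y) %in% nodes)) next
    if (am[x, y] == 1L && am[y, x] == 1L) {
      am[x, y] <- 0L # undirected pair: forbidden direction removed
    } else if (am[x, y] == 1L) {
      am[x, y] <- 0L
    }
  }
  wm <- constraints$whitelist
  for (k in seq_len(nrow(wm))) {
    x <- wm[k, 1]; y <- wm[k, 2]
    if (!all(c(x, y) %in% nodes)) stop2("whitelisted arc %s -> %s uses unknown nodes", x, y)
    am[x, y] <- 1L
    am[y, x] <- 0L
  }
  if (!is_acyclic_amat(am)) {
    stop2("expert constraints create a cycle with retained arcs",
          class = "exacnet_cycle_error")
  }
  graph_from_amat(am)
}

#' Write an arc strength table to CSV
#' @param strengths An `arc_strengths` table.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_strengths_csv <- function(strengths, path) {
  write.csv(as.data.frame(strengths), path, row.names = FALSE)
  invisible(path)
}
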