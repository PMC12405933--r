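# Fitted discrete Bayesian networks: CPT estimation, sampling, serialization.

new_dbn <- function(graph, levels, cpts, n = NA_integer_, alpha = NA_real_) {
  structure(list(graph = graph, levels = levels, cpts = cpts,
                 n = n, alpha = alpha),
            class = "exacnet_dbn")
}

#' @export
print.exacnet_dbn <- function(x, ...) {
  cat(sprintf("Discrete Bayesian network: %d nodes, %d arcs%s\n",
              length(x$graph$nodes), nrow(arcs(x$graph)),
              if (!is.na(x$n)) sprintf(" (fitted on n = %d, alpha = %g)", x$n, x$alpha) else ""))
  invisible(x)
}

#' Fit conditional probability tables on a DAG
#'
#' Estimates each node's CPT from discrete data: cell probability
#' \eqn{(N_{x|pa} + \alpha) / (N_{pa} + \alpha |X|)}. `smoothing_alpha = 0`
#' gives maximum-likelihood estimates; parent configurations never observed
#' then fall back to uniform rows with a warning. `smoothing_alpha = 1`
#' (Laplace, the default) avoids zero cells in prediction.
#'
#' @param dag A `bn_graph` DAG whose nodes are columns of `data`.
#' @param data Data frame of factors.
#' @param smoothing_alpha Additive smoothing pseudo-count (default 1).
#' @return An `exacnet_dbn`.
#' @export
fit_cpts <- function(dag, data, smoothing_alpha = 1) {
  stopifnot(smoothing_alpha >= 0)
  if (!is_dag(dag)) stop2("fit_cpts() requires a DAG; orient the network first (pdag_to_dag)")
  dd <- as_discrete_data(data)
  miss <- setdiff(dag$nodes, dd$nodes)
  if (length(miss)) stop2("node(s) not in data: %s", paste(miss, collapse = ", "))
  cpts <- list()
  for (nd in dag$nodes) {
    pa <- parents(dag, nd)
    cnt <- family_counts(dd, nd, pa)
    nx <- nrow(cnt)
    tot <- colSums(cnt)
    if (smoothing_alpha == 0 && any(tot == 0)) {
      warning(sprintf("node '%s': %d unobserved parent configuration(s) set to uniform",
                      nd, sum(tot == 0)))
      p <- sweep(cnt, 2, pmax(tot, 1), "/")
      p[, tot == 0] <- 1 / nx
    } else {
      p <- sweep(cnt + smoothing_alpha, 2, tot + smoothing_alpha * nx, "/")
    }
    a <- array(p, dim = c(nx, unname(dd$nlev[pa])),
               dimnames = c(list(dd$levels[[nd]]), unname(dd$levels[pa])))
    names(dimnames(a)) <- c(nd, pa)
    cpts[[nd]] <- a
  }
  new_dbn(dag, dd$levels[dag$nodes], cpts, n = dd$n, alpha = smoothing_alpha)
}

#' Sample from a fitted discrete network
#'
#' Ancestral sampling in topological order.
#'
#' @param net An `exacnet_dbn`.
#' @param n Number of rows.
#' @param seed Integer seed.
#' @return Data frame of factors.
#' @export
sample_from_net <- function(net, n, seed) {
  withr::with_seed(seed, {
    ord <- topo_sort(net$graph)
    out <- list()
    for (nd in ord) {
      cpt <- net$cpts[[nd]]
      pa <- names(dimnames(cpt))[-1] # CPT's own parent order
      nx <- length(net$levels[[nd]])
      m <- matrix(cpt, nrow = nx)
      if (length(pa)) {
        codes <- vapply(pa, function(p) as.integer(out[[p]]), integer(n))
        if (n == 1L) codes <- matrix(codes, nrow = 1L)
        cfg <- cfg_index_codes(codes, vapply(net$levels[pa], length, 1L))
      } else cfg <- rep(1L, n)
      u <- runif(n)
      cum <- apply(m, 2, cumsum)
      code <- as.integer(rowSums(u > t(cum)[cfg, , drop = FALSE])) + 1L
      out[[nd]] <- factor(net$levels[[nd]][code], levels = net$levels[[nd]])
    }
    as.data.frame(out)[net$graph$nodes]
  })
}

#' Random discrete network
#'
#' Draws a random DAG (each possible arc kept with probability `p_arc`,
#' orientation following a random node order) and Dirichlet(1) CPTs.
#' Used as a test-bed for the inference engine.
#'
#' @param n_nodes Number of nodes.
#' @param max_levels Levels per node are drawn uniformly from 2..`max_levels`.
#' @param seed Integer seed.
#' @param p_arc Arc inclusion probability (default 0.35).
#' @param concentration Dirichlet concentration for CPT rows; values below 1
#'   give spiky rows, i.e. strong dependencies (default 1).
#' @return An `exacnet_dbn`.
#' @export
random_discrete_net <- function(n_nodes, max_levels = 3L, seed, p_arc = 0.35,
                                concentration = 1) {
  withr::with_seed(seed, {
    nodes <- sprintf("N%02d", seq_len(n_nodes))
    ord <- sample(nodes)
    arcs <- NULL
    for (i in seq_len(n_nodes - 1L)) for (j in (i + 1L):n_nodes) {
      if (runif(1) < p_arc) arcs <- rbind(arcs, c(ord[i], ord[j]))
    }
    g <- bn_graph(nodes, arcs = arcs)
    levels <- lapply(nodes, function(nd) {
      k <- sample(2:max_levels, 1L)
      paste0("l", seq_len(k))
    })
    names(levels) <- nodes
    cpts <- list()
    for (nd in nodes) {
      pa <- parents(g, nd)
      nx <- length(levels[[nd]])
      ncfg <- ncfg_of(vapply(levels[pa], length, 1L))
      m <- matrix(rgamma(nx * ncfg, shape = concentration), nx, ncfg)
      m <- pmax(m, 1e-12) # Dirichlet(concentration) columns
      m <- sweep(m, 2, colSums(m), "/")
      a <- array(m, dim = c(nx, vapply(levels[pa], length, 1L)),
                 dimnames = c(list(levels[[nd]]), unname(levels[pa])))
      names(dimnames(a)) <- c(nd, pa)
      cpts[[nd]] <- a
    }
    new_dbn(g, levels, cpts)
  })
}

#' Serialize / load a fitted network as JSON
#' @param net An `exacnet_dbn`.
#' @param path File path.
#' @return `path` (write) or an `exacnet_dbn` (read).
#' @export
write_dbn_json <- function(net, path) {
  ser <- list(
    nodes = net$graph$nodes,
    arcs = as.data.frame(arcs(net$graph)),
    levels = net$levels,
    n = net$n, alpha = net$alpha,
    cpts = lapply(net$graph$nodes, function(nd)
      list(node = nd, parents = parents(net$graph, nd),
           probs = as.vector(net$cpts[[nd]])))
  )
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dbn_json
#' @export
read_dbn_json <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  arcs <- if (NROW(ser$arcs)) as.matrix(ser$arcs) else NULL
  g <- bn_graph(ser$nodes, arcs = arcs)
  levels <- lapply(ser$levels, as.character)
  cpts <- list()
  for (k in seq_len(NROW(ser$cpts))) {
    entry <- if (is.data.frame(ser$cpts)) ser$cpts[k, ] else ser$cpts[[k]]
    nd <- unlist(entry$node)
    pa <- as.character(unlist(entry$parents))
    nx <- length(levels[[nd]])
    a <- array(as.numeric(unlist(entry$probs)),
               dim = c(nx, vapply(levels[pa], length, 1L)),
               dimnames = c(list(levels[[nd]]), unname(levels[pa])))
    names(dimnames(a)) <- c(nd, pa)
    cpts[[nd]] <- a
  }
  new_dbn(g, levels, cpts, n = ser$n %||% NA_integer_, alpha = ser$alpha %||% NA_real_)
}
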