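# Influence diagrams: a discrete network extended with decision nodes
# (finite action sets) and utility nodes (real-valued tables over parent
# configurations, sign convention utility minus cost).

#' Build an influence diagram
#'
#' Extends a fitted discrete network with decision and utility nodes.
#' Decision nodes are chance-free: their action is chosen by a policy,
#' possibly conditional on observed parents. Utility nodes are sinks whose
#' tables assign a real value (utility minus cost) to each parent
#' configuration; the diagram's value is the sum over utility nodes.
#'
#' @param net An `exacnet_dbn` (chance nodes). CPTs of chance nodes may
#'   list decision nodes among their parents.
#' @param decisions Named list; each entry `list(actions = <levels>,
#'   parents = <information parents, possibly empty>)`.
#' @param utilities Named list; each entry `list(parents = <node names>,
#'   table = <numeric array over parent configurations, first parent
#'   fastest>)`.
#' @return An `exacnet_infdiag` object.
#' @export
influence_diagram <- function(net, decisions = list(), utilities = list()) {
  stopifnot(inherits(net, "exacnet_dbn"))
  all_named <- c(net$graph$nodes, names(decisions))
  for (dn in names(decisions)) {
    d <- decisions[[dn]]
    if (is.null(d$actions) || length(d$actions) < 1L) stop2("decision '%s' needs actions", dn)
    bad <- setdiff(d$parents %||% character(0), all_named)
    if (length(bad)) stop2("decision '%s' has unknown parent(s): %s", dn,
                           paste(bad, collapse = ", "))
  }
  for (un in names(utilities)) {
    u <- utilities[[un]]
    bad <- setdiff(u$parents, all_named)
    if (length(bad)) stop2("utility '%s' has unknown parent(s): %s", un,
                           paste(bad, collapse = ", "))
    if (!is.numeric(u$table) || any(!is.finite(u$table))) {
      stop2("utility '%s' table must be finite numeric", un)
    }
  }
  structure(list(net = net, decisions = decisions, utilities = utilities),
            class = "exacnet_infdiag")
}

#' @export
print.exacnet_infdiag <- function(x, ...) {
  cat(sprintf("Influence diagram: %d chance, %d decision, %d utility node(s)\n",
              length(x$net$graph$nodes), length(x$decisions), length(x$utilities)))
  invisible(x)
}

# all levels (chance + decision) for configuration enumeration
id_levels <- function(diagram) {
  lv <- diagram$net$levels
  for (dn in names(diagram$decisions)) lv[[dn]] <- diagram$decisions[[dn]]$actions
  lv
}

# enumerate policies: list of assignments action-index per information state
enumerate_policies <- function(diagram) {
  lv <- id_levels(diagram)
  per_dec <- lapply(names(diagram$decisions), function(dn) {
    d <- diagram$decisions[[dn]]
    nstate <- ncfg_of(vapply(lv[d$parents %||% character(0)], length, 1L))
    grids <- expand.grid(rep(list(seq_along(d$actions)), nstate))
    lapply(seq_len(nrow(grids)), function(r) as.integer(grids[r, ]))
  })
  names(per_dec) <- names(diagram$decisions)
  combos <- expand.grid(lapply(per_dec, seq_along))
  lapply(seq_len(nrow(combos)), function(r) {
    pol <- lapply(names(per_dec), function(dn) per_dec[[dn]][[combos[r, dn]]])
    names(pol) <- names(per_dec)
    pol
  })
}

# expected total utility of a fully specified policy (enumeration)
policy_expected_utility <- function(diagram, policy) {
  lv <- id_levels(diagram)
  net <- diagram$net
  nodes <- c(net$graph$nodes, names(diagram$decisions))
  nlev <- vapply(lv[nodes], length, 1L)
  grid <- as.matrix(expand.grid(lapply(nlev, seq_len), KEEP.OUT.ATTRS = FALSE))
  prob <- rep(1, nrow(grid))
  for (nd in net$graph$nodes) {
    pa <- names(dimnames(net$cpts[[nd]]))[-1]
    m <- matrix(net$cpts[[nd]], nrow = nlev[nd])
    cfg <- cfg_index_codes(grid[, pa, drop = FALSE], unname(nlev[pa]))
    prob <- prob * m[cbind(grid[, nd], cfg)]
  }
  for (dn in names(diagram$decisions)) {
    d <- diagram$decisions[[dn]]
    ip <- d$parents %||% character(0)
    state <- cfg_index_codes(grid[, ip, drop = FALSE], unname(nlev[ip]))
    chosen <- policy[[dn]][state]
    prob <- prob * (grid[, dn] == chosen)
  }
  total <- 0
  for (un in names(diagram$utilities)) {
    u <- diagram$utilities[[un]]
    cfg <- cfg_index_codes(grid[, u$parents, drop = FALSE], unname(nlev[u$parents]))
    total <- total + sum(prob * as.vector(u$table)[cfg])
  }
  total
}

#' Evaluate an influence diagram
#'
#' Expected total utility of a policy, or the optimal policy by exhaustive
#' enumeration over all deterministic policies (suited to the small diagrams
#' used here, typically one treatment decision).
#'
#' @param diagram An `exacnet_infdiag`.
#' @param policy `"optimal"`, or a named list giving, per decision node, an
#'   integer vector of action indices (one per information-parent
#'   configuration, first parent fastest) or a single action label applied
#'   unconditionally.
#' @return List with `expected_utility` and `policy` (per decision node, the
#'   chosen action labels per information state).
#' @export
evaluate_influence_diagram <- function(diagram, policy = "optimal") {
  stopifnot(inherits(diagram, "exacnet_infdiag"))
  lv <- id_levels(diagram)
  normalize_policy <- function(pol) {
    out <- list()
    for (dn in names(diagram$decisions)) {
      d <- diagram$decisions[[dn]]
      nstate <- ncfg_of(vapply(lv[d$parents %||% character(0)], length, 1L))
      pv <- pol[[dn]]
      if (is.null(pv)) stop2("policy missing an action for decision '%s'", dn)
      if (is.character(pv) && length(pv) == 1L) {
        ai <- match(pv, d$actions)
        if (is.na(ai)) stop2("unknown action '%s' for decision '%s'", pv, dn)
        pv <- rep(ai, nstate)
      }
      if (length(pv) != nstate) {
        stop2("policy for '%s' must cover all %d information state(s)", dn, nstate)
      }
      out[[dn]] <- as.integer(pv)
    }
    out
  }
  if (identical(policy, "optimal")) {
    pols <- enumerate_policies(diagram)
    if (!length(pols)) pols <- list(list())
    eus <- vapply(pols, function(p) policy_expected_utility(diagram, p), 1.0)
    best <- which.max(eus)
    pol <- pols[[best]]
    eu <- eus[best]
  } else {
    pol <- normalize_policy(policy)
    eu <- policy_expected_utility(diagram, pol)
  }
  labelled <- lapply(names(diagram$decisions), function(dn)
    diagram$decisions[[dn]]$actions[pol[[dn]]])
  names(labelled) <- names(diagram$decisions)
  list(expected_utility = eu, policy = labelled)
}
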