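# Exact inference: variable elimination over named-dimension factors, with a
# brute-force enumeration engine kept separate as an independent reference.

factor_vars <- function(f) names(dimnames(f))

factor_product <- function(f1, f2) {
  v1 <- factor_vars(f1); v2 <- factor_vars(f2)
  all_v <- union(v1, v2)
  dn <- c(dimnames(f1), dimnames(f2))[all_v]
  dims <- vapply(dn, length, 1L)
  grid <- as.matrix(expand.grid(lapply(dims, seq_len), KEEP.OUT.ATTRS = FALSE))
  val <- f1[grid[, v1, drop = FALSE]] * f2[grid[, v2, drop = FALSE]]
  array(val, dim = dims, dimnames = dn)
}

factor_marginalize <- function(f, var) {
  vars <- factor_vars(f)
  rest <- setdiff(vars, var)
  if (!length(rest)) return(sum(f))
  fp <- aperm(f, c(var, rest))
  nlev <- dim(f)[match(var, vars)]
  m <- matrix(fp, nrow = nlev)
  out <- colSums(m)
  dn <- dimnames(f)[rest]
  array(out, dim = vapply(dn, length, 1L), dimnames = dn)
}

factor_reduce <- function(f, var, level) {
  vars <- factor_vars(f)
  if (!var %in% vars) return(f)
  idx <- rep(list(quote(expr = )), length(vars))
  pos <- match(level, dimnames(f)[[var]])
  if (is.na(pos)) stop2("level '%s' not valid for '%s'", level, var)
  idx[[match(var, vars)]] <- pos
  out <- do.call(`[`, c(list(f), idx, list(drop = FALSE)))
  rest <- setdiff(vars, var)
  if (!length(rest)) return(sum(out))
  dn <- dimnames(f)[rest]
  array(as.vector(aperm(out, c(rest, var))), dim = vapply(dn, length, 1L), dimnames = dn)
}

check_evidence <- function(net, evidence, query = NULL) {
  if (is.null(evidence) || !length(evidence)) return(list())
  ev <- as.list(evidence)
  ev <- ev[!vapply(ev, function(x) is.null(x) || is.na(x), TRUE)]
  bad <- setdiff(names(ev), net$graph$nodes)
  if (length(bad)) stop2("evidence on unknown node(s): %s", paste(bad, collapse = ", "))
  if (!is.null(query) && query %in% names(ev)) {
    stop2("evidence on the query node '%s' is not allowed", query)
  }
  for (nd in names(ev)) {
    lv <- as.character(ev[[nd]])
    if (!lv %in% net$levels[[nd]]) {
      stop2("level '%s' is not a fitted level of node '%s'", lv, nd)
    }
    ev[[nd]] <- lv
  }
  ev
}

#' Exact posterior by variable elimination
#'
#' Computes \eqn{P(query \mid evidence)} in a fitted discrete network by
#' factor multiplication and summation along a min-degree elimination order
#' (deterministic tie-break by node name). Exact answers do not depend on
#' the order; it affects speed only.
#'
#' @param net An `exacnet_dbn`.
#' @param query_node Node whose posterior is requested.
#' @param evidence Named list/vector of observed levels (possibly empty);
#'   must not include the query node.
#' @return Named probability vector over the query node's levels.
#' @examples
#' net <- random_discrete_net(4, seed = 1)
#' variable_elimination(net, net$graph$nodes[1])
#' @export
variable_elimination <- function(net, query_node, evidence = list()) {
  stopifnot(inherits(net, "exacnet_dbn"))
  if (!query_node %in% net$graph$nodes) stop2("unknown query node '%s'", query_node)
  ev <- check_evidence(net, evidence, query = query_node)
  factors <- net$cpts
  const <- 1
  for (nd in names(ev)) {
    factors <- lapply(factors, factor_reduce, var = nd, level = ev[[nd]])
  }
  scalars <- vapply(factors, function(f) is.null(dim(f)), TRUE)
  const <- prod(unlist(factors[scalars]), 1)
  factors <- factors[!scalars]
  to_eliminate <- setdiff(net$graph$nodes, c(query_node, names(ev)))
  while (length(to_eliminate)) {
    scopes <- lapply(factors, factor_vars)
    # min-degree: variable appearing with the fewest distinct neighbours
    degree <- vapply(to_eliminate, function(v) {
      nb <- unique(unlist(scopes[vapply(scopes, function(s) v %in% s, TRUE)]))
      length(setdiff(nb, v))
    }, 1L)
    v <- to_eliminate[order(degree, to_eliminate)][1L]
    involved <- vapply(scopes, function(s) v %in% s, TRUE)
    if (any(involved)) {
      f <- Reduce(factor_product, factors[involved])
      f <- factor_marginalize(f, v)
      factors <- factors[!involved]
      if (is.null(dim(f))) const <- const * f else factors[[length(factors) + 1L]] <- f
    }
    to_eliminate <- setdiff(to_eliminate, v)
  }
  out <- if (length(factors)) Reduce(factor_product, factors) else {
    stop2("query node carries no remaining factor; inconsistent network")
  }
  if (!identical(factor_vars(out), query_node)) {
    out <- aperm(out, query_node)
  }
  p <- as.vector(out) * const
  z <- sum(p)
  if (!is.finite(z) || z <= 0) {
    stop2("evidence has zero probability under the network (inconsistent evidence)",
          class = "exacnet_evidence_error")
  }
  setNames(p / z, net$levels[[query_node]])
}

#' Posterior by brute-force joint enumeration
#'
#' Builds the full joint table by the chain rule and conditions directly.
#' Exponential in the number of nodes; retained as an independent reference
#' implementation for the elimination engine.
#'
#' @inheritParams variable_elimination
#' @return Named probability vector over the query node's levels.
#' @export
enumerate_posterior <- function(net, query_node, evidence = list()) {
  stopifnot(inherits(net, "exacnet_dbn"))
  ev <- check_evidence(net, evidence, query = query_node)
  nodes <- net$graph$nodes
  nlev <- vapply(net$levels, length, 1L)[nodes]
  grid <- as.matrix(expand.grid(lapply(nlev, seq_len), KEEP.OUT.ATTRS = FALSE))
  prob <- rep(1, nrow(grid))
  for (nd in nodes) {
    pa <- names(dimnames(net$cpts[[nd]]))[-1] # CPT's own parent order
    m <- matrix(net$cpts[[nd]], nrow = nlev[nd])
    cfg <- cfg_index_codes(grid[, pa, drop = FALSE], unname(nlev[pa]))
    prob <- prob * m[cbind(grid[, nd], cfg)]
  }
  keep <- rep(TRUE, nrow(grid))
  for (nd in names(ev)) {
    keep <- keep & grid[, nd] == match(ev[[nd]], net$levels[[nd]])
  }
  num <- tapply(prob[keep], grid[keep, query_node], sum)
  p <- numeric(nlev[query_node])
  p[as.integer(names(num))] <- num
  z <- sum(p)
  if (z <= 0) stop2("evidence has zero probability under the network (inconsistent evidence)",
                    class = "exacnet_evidence_error")
  setNames(p / z, net$levels[[query_node]])
}

#' Joint probability of a complete assignment (chain rule)
#'
#' @param net An `exacnet_dbn`.
#' @param assignment Named character vector assigning a level to every node.
#' @return A single probability.
#' @export
joint_probability <- function(net, assignment) {
  nodes <- net$graph$nodes
  stopifnot(setequal(names(assignment), nodes))
  p <- 1
  for (nd in nodes) {
    pa <- names(dimnames(net$cpts[[nd]]))[-1]
    idx <- c(match(assignment[[nd]], net$levels[[nd]]),
             vapply(pa, function(q) match(assignment[[q]], net$levels[[q]]), 1L))
    p <- p * net$cpts[[nd]][matrix(idx, nrow = 1L)]
  }
  unname(p)
}

#' Predict severe-exacerbation risk for patients
#'
#' Posterior over the 3-level outcome via [variable_elimination()], with the
#' derived risks P(>=1) and P(>=2). Evidence nodes missing from a patient's
#' record are marginalized over. Rows with identical evidence are grouped so
#' cohort-scale prediction stays fast.
#'
#' @param net An `exacnet_dbn` containing the outcome node.
#' @param patient_evidence A data frame of factor columns (one row per
#'   patient; columns not in the network are ignored) or a single named list.
#' @param outcome Outcome node name (default `"future_exac"`).
#' @return A data frame with one row per patient: the outcome-level
#'   probabilities, `p_ge1` and `p_ge2`.
#' @export
predict_exacerbation_risk <- function(net, patient_evidence, outcome = "future_exac") {
  if (!outcome %in% net$graph$nodes) stop2("outcome node '%s' not in network", outcome)
  lv <- net$levels[[outcome]]
  if (!is.data.frame(patient_evidence)) {
    patient_evidence <- as.data.frame(lapply(patient_evidence, as.character),
                                      stringsAsFactors = FALSE)
  }
  use <- intersect(names(patient_evidence), setdiff(net$graph$nodes, outcome))
  n_in <- max(nrow(patient_evidence), 1L)
  if (!length(use)) {
    # no evidence columns: cohort-marginal outcome distribution per row
    m <- variable_elimination(net, outcome)
    out <- as.data.frame(matrix(rep(m, each = n_in), nrow = n_in))
    names(out) <- paste0("p_", lv)
    out$p_ge1 <- rowSums(out[, -1, drop = FALSE])
    out$p_ge2 <- if (length(lv) >= 3) rowSums(out[, seq(3, length(lv)), drop = FALSE]) else 0
    return(out)
  }
  evm <- as.data.frame(lapply(patient_evidence[use], as.character),
                       stringsAsFactors = FALSE)
  if (!nrow(evm)) stop2("no usable evidence rows")
  key <- do.call(paste, c(evm, sep = "\r"))
  uk <- !duplicated(key)
  probs <- matrix(NA_real_, sum(uk), length(lv))
  urows <- which(uk)
  for (i in seq_along(urows)) {
    ev <- as.list(evm[urows[i], , drop = FALSE])
    probs[i, ] <- variable_elimination(net, outcome, ev)
  }
  map <- match(key, key[uk])
  out <- as.data.frame(probs[map, , drop = FALSE])
  names(out) <- paste0("p_", lv)
  # risk cuts: P(>=1) and P(>=2) assume levels ordered 0 / 1 / 2+
  out$p_ge1 <- rowSums(out[, -1, drop = FALSE])
  out$p_ge2 <- if (length(lv) >= 3) rowSums(out[, seq(3, length(lv)), drop = FALSE]) else 0
  out
}
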