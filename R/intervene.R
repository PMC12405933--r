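# Counterfactual interventions: graph mutilation (do-operator).

#' Intervene on a node (do-operator)
#'
#' Graph mutilation: removes all arcs into `node` and replaces its CPT by a
#' point mass at `level`; every other CPT is unchanged. Downstream
#' distributions respond, non-descendants are unaffected.
#'
#' @param net An `exacnet_dbn`.
#' @param node Node to intervene on.
#' @param level Level to set it to.
#' @return A mutilated `exacnet_dbn`.
#' @export
intervene_do <- function(net, node, level) {
  stopifnot(inherits(net, "exacnet_dbn"))
  if (!node %in% net$graph$nodes) stop2("unknown node '%s'", node)
  lv <- net$levels[[node]]
  if (!level %in% lv) stop2("level '%s' is not a level of node '%s'", level, node)
  am <- net$graph$amat
  am[, node] <- 0L
  net$graph <- graph_from_amat(am)
  p <- as.numeric(lv == level)
  a <- array(p, dim = length(lv), dimnames = list(lv))
  names(dimnames(a)) <- node
  net$cpts[[node]] <- a
  net
}

#' Compare target distributions across interventions
#'
#' Applies [intervene_do()] at each requested level of a node and reports
#' the target's marginal under each intervention, with deltas against the
#' first level (the counterfactual reference).
#'
#' @param net An `exacnet_dbn`.
#' @param node Intervention node (e.g. CRS status).
#' @param levels Two or more levels to set (the first is the reference).
#' @param target Target node (e.g. future exacerbations).
#' @return Data frame: one row per intervention level, columns for each
#'   target-level probability, `p_ge1` where applicable, and deltas.
#' @export
counterfactual_compare <- function(net, node, levels, target) {
  if (length(levels) < 1L) stop2("at least one intervention level required")
  tl <- net$levels[[target]]
  m <- t(vapply(levels, function(l)
    variable_elimination(intervene_do(net, node, l), target), numeric(length(tl))))
  out <- data.frame(level = as.character(levels), stringsAsFactors = FALSE,
                    check.names = FALSE)
  for (j in seq_along(tl)) out[[paste0("p_", tl[j])]] <- m[, j]
  if (length(tl) >= 2L) out$p_ge1 <- rowSums(m[, -1, drop = FALSE])
  for (cn in setdiff(names(out), "level")) {
    out[[paste0("delta_", sub("^p_", "", cn))]] <- out[[cn]] - out[[cn]][1]
  }
  out
}
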