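# Decomposable network scores for discrete Bayesian networks.

#' Family score of a node given a parent set
#'
#' Local (per-family) contribution to a decomposable network score.
#' `"bic"` is the log-likelihood of the node given its parent configurations
#' minus \eqn{(\ln n / 2)} times the number of free parameters
#' \eqn{(|X|-1)\prod_j |Pa_j|}; `"bdeu"` is the Dirichlet-multinomial
#' marginal log-likelihood with equivalent sample size `ess` split uniformly
#' over cells.
#'
#' @param node Node name.
#' @param parents Character vector of parent names (possibly empty).
#' @param data Data frame of factors.
#' @param score `"bic"` or `"bdeu"`.
#' @param ess Equivalent sample size for BDeu (default 1).
#' @return A single numeric score (larger is better).
#' @examples
#' d <- data.frame(a = factor(rep(c("y", "n"), c(60, 40))))
#' family_score("a", character(0), d) # 60*log(.6) + 40*log(.4) - log(100)/2
#' @export
family_score <- function(node, parents = character(0), data, score = c("bic", "bdeu"), ess = 1) {
  score <- match.arg(score)
  dd <- as_discrete_data(data)
  family_score_dd(dd, node, parents, score, ess)
}

family_score_dd <- function(dd, node, parents, score, ess = 1) {
  if (!is.null(dd$cache)) {
    key <- paste0("fs|", score, "|", node, "|", paste(sort(parents), collapse = ","))
    hit <- dd$cache[[key]]
    if (!is.null(hit)) return(hit)
  }
  w <- dd$w %||% rep(1, nrow(dd$m))
  out <- cpp_family_score(dd$m, w, match(node, dd$nodes) - 1L,
                          match(parents, dd$nodes) - 1L, unname(dd$nlev),
                          if (score == "bic") 0L else 1L, ess, dd$n)
  if (!is.null(dd$cache)) dd$cache[[key]] <- out
  out
}

#' Total score of a DAG on discrete data
#'
#' Sum of [family_score()] terms over all nodes (decomposability).
#'
#' @param g A `bn_graph` DAG whose nodes are columns of `data`.
#' @param data Data frame of factors.
#' @inheritParams family_score
#' @return A single numeric score.
#' @export
network_score <- function(g, data, score = c("bic", "bdeu"), ess = 1) {
  score <- match.arg(score)
  dd <- as_discrete_data(data)
  sum(vapply(g$nodes, function(nd) family_score_dd(dd, nd, parents(g, nd), score, ess), 1.0))
}
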