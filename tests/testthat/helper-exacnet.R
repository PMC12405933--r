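# Shared fixtures, all built in code. The core9 spec and derived objects are
# memoized per test file to keep the suite fast.

.fixtures <- new.env(parent = emptyenv())

core9_spec <- function() {
  if (is.null(.fixtures$spec)) .fixtures$spec <- make_ground_truth_network("core9")
  .fixtures$spec
}

core9_cohort <- function(n = 20000, seed = 11) {
  key <- paste0("coh_", n, "_", seed)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- sample_cohort(core9_spec(), n, seed)
  }
  .fixtures[[key]]
}

core9_discrete <- function(n = 20000, seed = 11) {
  key <- paste0("dd_", n, "_", seed)
  if (is.null(.fixtures[[key]])) {
    co <- core9_cohort(n, seed)
    .fixtures[[key]] <- discretize_clinical(co)$data[
      setdiff(names(core9_spec()$nodes), "country")]
  }
  .fixtures[[key]]
}

# concordant-pair AUC oracle (ties count one half); independent of the
# rank-based implementation under test
auc_pair_oracle <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# tiny two-node chain network P(A=1)=.6, P(B=1|A=1)=.9, P(B=1|A=0)=.2
chain_net_ab <- function() {
  g <- bn_graph(c("A", "B"), arcs = rbind(c("A", "B")))
  lv <- list(A = c("0", "1"), B = c("0", "1"))
  cptA <- array(c(0.4, 0.6), dim = 2, dimnames = list(c("0", "1")))
  names(dimnames(cptA)) <- "A"
  cptB <- array(c(0.8, 0.2, 0.1, 0.9), dim = c(2, 2),
                dimnames = list(c("0", "1"), c("0", "1")))
  names(dimnames(cptB)) <- c("B", "A")
  exacnet:::new_dbn(g, lv, list(A = cptA, B = cptB))
}

# data frame of n samples from a dependent pair A -> B with given strengths
sample_pair <- function(n, seed, p_hi = 0.9, p_lo = 0.1) {
  withr::with_seed(seed, {
    a <- factor(sample(c("0", "1"), n, TRUE))
    b <- factor(ifelse(runif(n) < ifelse(a == "1", p_hi, p_lo), "1", "0"))
    data.frame(A = a, B = b)
  })
}

sample_independent <- function(n, seed, p = 3) {
  withr::with_seed(seed, {
    out <- as.data.frame(lapply(seq_len(p), function(i)
      factor(sample(c("a", "b", "c")[1:min(3, 1 + i %% 3 + 1)], n, TRUE))))
    names(out) <- paste0("V", seq_len(p))
    out
  })
}
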