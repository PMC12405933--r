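test_that("hill climbing recovers a strong pairwise dependence", {
  hits <- 0L
  true_cp <- cpdag_of(bn_graph(c("A", "B"), arcs = rbind(c("A", "B"))))
  for (s in 1:20) {
    d <- sample_pair(5000, seed = s)
    g <- hill_climb(d)
    if (nrow(arcs(g)) == 1L && shd(cpdag_of(g), true_cp) == 0L) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("hill climbing returns the empty graph on independent data", {
  empties <- 0L
  for (s in 1:20) {
    d <- withr::with_seed(s, data.frame(
      A = factor(sample(c("x", "y"), 5000, TRUE)),
      B = factor(sample(c("x", "y", "z"), 5000, TRUE)),
      C = factor(sample(c("x", "y"), 5000, TRUE))))
    if (nrow(arcs(hill_climb(d))) == 0L) empties <- empties + 1L
  }
  expect_gte(empties, 18L)
})

test_that("constraints are honoured and validated", {
  d <- withr::with_seed(1, data.frame(
    A = factor(sample(c("x", "y"), 2000, TRUE)),
    B = factor(sample(c("x", "y"), 2000, TRUE))))
  g <- hill_climb(d, whitelist = rbind(c("A", "B")))
  expect_true(any(arcs(g)[, 1] == "A" & arcs(g)[, 2] == "B"))
  expect_error(hill_climb(d, whitelist = rbind(c("A", "B"), c("B", "A"))),
               class = "exacnet_cycle_error")
  d2 <- sample_pair(3000, seed = 2)
  g2 <- hill_climb(d2, blacklist = rbind(c("A", "B")))
  expect_false(any(arcs(g2)[, 1] == "A" & arcs(g2)[, 2] == "B"))
})

test_that("learned score never falls below the empty network", {
  for (s in 1:5) {
    d <- core9_discrete(3000, seed = 60 + s)
    g <- hill_climb(d)
    empty <- network_score(bn_graph(names(d)), d)
    expect_gte(attr(g, "score"), empty)
    # decomposability: reported score equals recomputed network score
    expect_equal(attr(g, "score"), network_score(g, d), tolerance = 1e-9)
  }
})

test_that("tabu search never scores worse than plain hill climbing", {
  for (s in 1:5) {
    d <- core9_discrete(3000, seed = 70 + s)
    s_hc <- attr(hill_climb(d), "score")
    s_tabu <- attr(hill_climb(d, tabu_length = 10), "score")
    expect_gte(s_tabu, s_hc - 1e-9)
  }
})

test_that("hill climbing is deterministic given identical input", {
  d <- core9_discrete(2000, seed = 80)
  expect_identical(hill_climb(d)$amat, hill_climb(d)$amat)
})
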