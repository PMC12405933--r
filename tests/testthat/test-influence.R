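test_that("expected utility of a single chance node is the weighted sum", {
  g <- bn_graph("S")
  cpt <- array(c(0.7, 0.2, 0.1), dim = 3, dimnames = list(c("a", "b", "c")))
  names(dimnames(cpt)) <- "S"
  net <- exacnet:::new_dbn(g, list(S = c("a", "b", "c")), list(S = cpt))
  id <- influence_diagram(net, utilities = list(
    u = list(parents = "S", table = c(1.0, 0.5, 0.0))))
  out <- evaluate_influence_diagram(id)
  expect_equal(out$expected_utility, 0.80, tolerance = 1e-12)
})

test_that("a state-wise dominant action is always chosen", {
  g <- bn_graph("S")
  cpt <- array(c(0.6, 0.4), dim = 2, dimnames = list(c("s1", "s2")))
  names(dimnames(cpt)) <- "S"
  net <- exacnet:::new_dbn(g, list(S = c("s1", "s2")), list(S = cpt))
  # utility table over (S, D): action a2 dominates in every state
  ut <- array(c(1, 0, 3, 2), dim = c(2, 2)) # S fastest
  id <- influence_diagram(net,
                          decisions = list(D = list(actions = c("a1", "a2"))),
                          utilities = list(u = list(parents = c("S", "D"),
                                                    table = ut)))
  out <- evaluate_influence_diagram(id)
  expect_equal(unname(out$policy$D), "a2")
  expect_equal(out$expected_utility, 0.6 * 3 + 0.4 * 2, tolerance = 1e-12)
  # explicit policies evaluate correctly too
  out1 <- evaluate_influence_diagram(id, policy = list(D = "a1"))
  expect_equal(out1$expected_utility, 0.6 * 1 + 0.4 * 0, tolerance = 1e-12)
})

test_that("optimal policies match exhaustive enumeration on random diagrams", {
  for (s in 1:5) {
    rn <- random_discrete_net(3, 3, seed = 60 + s)
    nodes <- rn$graph$nodes
    withr::with_seed(s, {
      acts <- c("treat", "wait", "refer")[1:sample(2:3, 1)]
      # utility over (last chance node, decision)
      nlev <- length(rn$levels[[nodes[3]]])
      ut <- runif(nlev * length(acts), -1, 1)
    })
    id <- influence_diagram(rn,
                            decisions = list(D = list(actions = acts,
                                                      parents = nodes[1])),
                            utilities = list(u = list(parents = c(nodes[3], "D"),
                                                      table = ut)))
    out <- evaluate_influence_diagram(id)
    # independent oracle: loop over every deterministic policy mapping
    n_states <- length(rn$levels[[nodes[1]]])
    combos <- expand.grid(rep(list(seq_along(acts)), n_states))
    eus <- apply(combos, 1, function(row) {
      exacnet:::policy_expected_utility(id, list(D = as.integer(row)))
    })
    expect_equal(out$expected_utility, max(eus), tolerance = 1e-9)
  }
})

test_that("invalid diagrams and incomplete policies are rejected", {
  net <- chain_net_ab()
  expect_error(influence_diagram(net, utilities = list(
    u = list(parents = "Z", table = 1:2))))
  id <- influence_diagram(net,
                          decisions = list(D = list(actions = c("x", "y"),
                                                    parents = "A")),
                          utilities = list(u = list(parents = c("B", "D"),
                                                    table = c(0, 1, 2, 3))))
  expect_error(evaluate_influence_diagram(id, policy = list(D = 1L)),
               "information state")
  expect_error(evaluate_influence_diagram(id, policy = list()))
})
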