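test_that("CPT fitting matches count ratios and smoothing limits", {
  d <- data.frame(A = factor(rep(c("0", "1"), c(20, 40))),
                  B = factor(c(rep("0", 15), rep("1", 5), rep("0", 10), rep("1", 30))))
  dag <- bn_graph(c("A", "B"), arcs = rbind(c("A", "B")))
  net <- fit_cpts(dag, d, smoothing_alpha = 0)
  expect_equal(unname(net$cpts$B["1", "1"]), 30 / 40) # P(B=1 | A=1)
  # alpha -> infinity: rows tend to uniform
  net_inf <- fit_cpts(dag, d, smoothing_alpha = 1e9)
  expect_equal(unname(net_inf$cpts$B[, "1"]), c(0.5, 0.5), tolerance = 1e-6)
  # every fitted column sums to one
  for (a in net$cpts) {
    m <- matrix(a, nrow = dim(a)[1])
    expect_true(all(abs(colSums(m) - 1) < 1e-12))
  }
  # unobserved parent configuration with alpha = 0: uniform with warning
  d2 <- data.frame(A = factor(rep("0", 10), levels = c("0", "1")),
                   B = factor(rep(c("0", "1"), 5)))
  expect_warning(net2 <- fit_cpts(dag, d2, smoothing_alpha = 0), "unobserved")
  expect_equal(unname(net2$cpts$B[, "1"]), c(0.5, 0.5))
})

test_that("variable elimination matches hand computation and the enumeration engine", {
  net <- chain_net_ab()
  expect_equal(unname(variable_elimination(net, "B")["1"]),
               0.6 * 0.9 + 0.4 * 0.2, tolerance = 1e-12)
  # random networks, random queries and evidence, against brute force
  for (s in 1:10) {
    rn <- random_discrete_net(6, 3, seed = s)
    q <- rn$graph$nodes[1 + s %% 6]
    ev <- list()
    ev_node <- setdiff(rn$graph$nodes, q)[1]
    ev[[ev_node]] <- rn$levels[[ev_node]][1]
    expect_equal(variable_elimination(rn, q, ev), enumerate_posterior(rn, q, ev),
                 tolerance = 1e-9)
    expect_equal(sum(variable_elimination(rn, q, ev)), 1, tolerance = 1e-12)
  }
  # evidence on the query is rejected; impossible evidence raises
  expect_error(variable_elimination(net, "B", list(B = "1")))
  net0 <- net
  net0$cpts$A[] <- c(1, 0) # A = "1" now impossible
  expect_error(variable_elimination(net0, "B", list(A = "1")),
               class = "exacnet_evidence_error")
})

test_that("chain rule joint probabilities agree with enumeration", {
  rn <- random_discrete_net(5, 3, seed = 11)
  nodes <- rn$graph$nodes
  withr::with_seed(1, {
    for (k in 1:10) {
      asg <- vapply(nodes, function(nd) sample(rn$levels[[nd]], 1), "")
      jp <- joint_probability(rn, asg)
      ev <- as.list(asg[-1])
      post <- enumerate_posterior(rn, nodes[1], ev)
      # P(full) = P(node1 = value | rest) * P(rest)
      prest <- sum(vapply(rn$levels[[nodes[1]]], function(l) {
        joint_probability(rn, replace(asg, 1, l))
      }, 1.0))
      expect_equal(jp, unname(post[asg[1]]) * prest, tolerance = 1e-12)
    }
  })
})

test_that("do-interventions mutilate the graph with correct semantics", {
  # do on a root equals conditioning on it
  rn <- random_discrete_net(6, 3, seed = 21)
  roots <- rn$graph$nodes[vapply(rn$graph$nodes, function(nd)
    length(parents(rn$graph, nd)) == 0L, TRUE)]
  r <- roots[1]
  lv <- rn$levels[[r]][1]
  q <- setdiff(rn$graph$nodes, r)[3]
  expect_equal(variable_elimination(intervene_do(rn, r, lv), q),
               variable_elimination(rn, q, setNames(list(lv), r)),
               tolerance = 1e-12)
  # do on a sink changes no other marginal
  sinks <- rn$graph$nodes[rowSums(rn$graph$amat) == 0]
  s <- sinks[1]
  net_do <- intervene_do(rn, s, rn$levels[[s]][1])
  for (q in setdiff(rn$graph$nodes, s)) {
    expect_equal(variable_elimination(net_do, q), variable_elimination(rn, q),
                 tolerance = 1e-12)
  }
  # non-descendant invariance across random DAGs
  for (s2 in 1:5) {
    rn2 <- random_discrete_net(6, 3, seed = 30 + s2)
    nd <- rn2$graph$nodes[3]
    net2 <- intervene_do(rn2, nd, rn2$levels[[nd]][1])
    desc <- exacnet:::descendants(rn2$graph, nd)
    for (q in setdiff(rn2$graph$nodes, c(nd, desc))) {
      expect_equal(variable_elimination(net2, q), variable_elimination(rn2, q),
                   tolerance = 1e-12)
    }
  }
  expect_error(intervene_do(rn, "N01", "not-a-level"))
})

test_that("fitted CPTs converge to the generator's tables", {
  spec <- core9_spec()
  truth <- true_discrete_net(spec)
  d <- sample_from_net(truth, 100000, seed = 41)
  net <- suppressWarnings(fit_cpts(truth$graph, d, smoothing_alpha = 0))
  for (nd in c("crs", "bec", "prior_exac")) {
    pa <- parents(truth$graph, nd)
    cnt <- exacnet:::family_counts(exacnet:::as_discrete_data(d), nd, pa)
    fitted <- matrix(net$cpts[[nd]], nrow = dim(net$cpts[[nd]])[1])
    # align the reference to the fitted CPT's parent-dimension order
    ref_a <- aperm(truth$cpts[[nd]], names(dimnames(net$cpts[[nd]])))
    ref <- matrix(ref_a, nrow = dim(ref_a)[1])
    # per-configuration bound: small systematic slack plus 3 binomial sds
    supp <- colSums(cnt)
    ok <- which(supp >= 2000)
    expect_true(length(ok) > 0)
    for (k in ok) {
      bound <- 0.004 + 3 * sqrt(0.25 / supp[k])
      expect_lt(max(abs(fitted[, k] - ref[, k])), bound)
    }
  }
})

test_that("risk prediction marginalizes missing evidence and matches CPT rows", {
  spec <- core9_spec()
  net <- true_discrete_net(spec)
  # empty evidence: the cohort-marginal outcome distribution
  marg <- variable_elimination(net, "future_exac")
  pr0 <- predict_exacerbation_risk(net, data.frame(unrelated = 1))
  expect_equal(unname(unlist(pr0[1, c("p_0", "p_1", "p_2+")])), unname(marg),
               tolerance = 1e-12)
  pr1 <- predict_exacerbation_risk(net, data.frame(age = factor("mid", c("low", "mid", "high"))))
  expect_equal(sum(pr1[1, c("p_0", "p_1", "p_2+")]), 1, tolerance = 1e-12)
  # evidence fixing all outcome parents returns exactly the CPT column
  pa <- parents(net$graph, "future_exac")
  ev <- lapply(net$levels[pa], `[`, 2)
  pr2 <- predict_exacerbation_risk(net, as.data.frame(ev))
  idx <- c(list(quote(expr = )), lapply(pa, function(p) 2L))
  ref <- do.call(`[`, c(list(net$cpts$future_exac), idx))
  expect_equal(unname(unlist(pr2[1, c("p_0", "p_1", "p_2+")])), as.vector(ref),
               tolerance = 1e-12)
  expect_true(pr2$p_ge1 >= pr2$p_ge2)
  # counterfactual comparison: repeated level has zero delta; a node with
  # no descendants leaves the target untouched
  cc <- counterfactual_compare(net, "crs", c("None", "None"), "future_exac")
  expect_equal(cc$delta_ge1[2], 0, tolerance = 1e-12)
  cc2 <- counterfactual_compare(net, "future_exac", c("0", "1", "2+"), "age")
  expect_equal(cc2$`delta_low`, rep(0, 3), tolerance = 1e-12)
})

test_that("network JSON serialization round-trips exactly", {
  rn <- random_discrete_net(5, 3, seed = 51)
  f <- tempfile(fileext = ".json")
  write_dbn_json(rn, f)
  back <- read_dbn_json(f)
  expect_equal(sort(back$graph$nodes), sort(rn$graph$nodes))
  for (nd in rn$graph$nodes) {
    expect_equal(back$cpts[[nd]], rn$cpts[[nd]], tolerance = 1e-12)
  }
  expect_equal(variable_elimination(back, rn$graph$nodes[2]),
               variable_elimination(rn, rn$graph$nodes[2]), tolerance = 1e-12)
})
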