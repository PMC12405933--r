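test_that("deterministic dependence reaches adjacency frequency one", {
  d <- withr::with_seed(1, {
    x <- factor(sample(c("a", "b"), 500, TRUE))
    data.frame(X = x, Y = x)
  })
  st <- bootstrap_strengths(d, algorithms = "hc", B = 10, seed = 2)
  expect_equal(st$adjacency_frequency[st$from == "X" & st$to == "Y"], 1.0)
})

test_that("independent variables stay below the selection threshold", {
  d <- withr::with_seed(2, data.frame(
    X = factor(sample(c("a", "b"), 5000, TRUE)),
    Y = factor(sample(c("a", "b"), 5000, TRUE))))
  st <- bootstrap_strengths(d, algorithms = "hc", B = 50, seed = 3)
  expect_lt(st$adjacency_frequency[st$from == "X" & st$to == "Y"], 0.25)
})

test_that("the default bootstrap configuration is 1000 replicates at 0.75", {
  expect_equal(eval(formals(bootstrap_strengths)$B), 1000L)
  expect_equal(eval(formals(averaged_network)$threshold), 0.75)
})

test_that("averaged_network thresholds adjacency and orients by majority", {
  nodes <- c("A", "B", "C")
  st <- data.frame(from = c("A", "B", "A", "C"), to = c("B", "A", "C", "A"),
                   adjacency_frequency = c(0.9, 0.9, 0.5, 0.5),
                   direction_frequency = c(0.8, 0.2, 0.5, 0.5))
  attr(st, "nodes") <- nodes
  g <- averaged_network(st, 0.75)
  expect_equal(unname(arcs(g)), cbind("A", "B"))
  expect_equal(nrow(undirected_edges(g)), 0L)
  # threshold 1 with all frequencies < 1: empty graph
  st$adjacency_frequency <- c(0.99, 0.99, 0.5, 0.5)
  expect_equal(nrow(arcs(averaged_network(st, 1.0))) +
                 nrow(undirected_edges(averaged_network(st, 1.0))), 0L)
  # 0.5/0.5 direction ties stay undirected
  st2 <- st
  st2$adjacency_frequency <- c(0.9, 0.9, 0.2, 0.2)
  st2$direction_frequency <- c(0.5, 0.5, 0.5, 0.5)
  g2 <- averaged_network(st2, 0.75)
  expect_equal(nrow(arcs(g2)), 0L)
  expect_equal(nrow(undirected_edges(g2)), 1L)
})

test_that("raising the threshold never adds edges", {
  d <- core9_discrete(5000, seed = 110)
  st <- bootstrap_strengths(d, algorithms = c("hc", "pc_stable"), B = 20, seed = 4)
  sizes <- vapply(seq(0.3, 1, by = 0.1), function(th) {
    g <- averaged_network(st, th)
    nrow(arcs(g)) + nrow(undirected_edges(g))
  }, 1L)
  expect_true(all(diff(sizes) <= 0L))
})

test_that("expert constraints edit the averaged network safely", {
  g <- bn_graph(c("anxiety", "future_exac", "prior_exac"),
                arcs = rbind(c("anxiety", "future_exac")))
  ec <- expert_constraints(whitelist = rbind(c("prior_exac", "future_exac")),
                           blacklist = rbind(c("anxiety", "future_exac")))
  out <- apply_expert_constraints(g, ec)
  a <- apply(arcs(out), 1, paste, collapse = ">")
  expect_false("anxiety>future_exac" %in% a)
  expect_true("prior_exac>future_exac" %in% a)
  # empty constraints: identity
  expect_identical(apply_expert_constraints(g, expert_constraints())$amat, g$amat)
  # whitelist/blacklist overlap and whitelist cycles are rejected
  expect_error(expert_constraints(whitelist = rbind(c("a", "b")),
                                  blacklist = rbind(c("a", "b"))))
  expect_error(expert_constraints(whitelist = rbind(c("a", "b"), c("b", "a"))),
               class = "exacnet_cycle_error")
  # whitelist creating a cycle with retained arcs
  g2 <- bn_graph(c("a", "b", "c"), arcs = rbind(c("a", "b"), c("b", "c")))
  ec2 <- expert_constraints(whitelist = rbind(c("c", "a")))
  expect_error(apply_expert_constraints(g2, ec2), class = "exacnet_cycle_error")
})

test_that("strength tables export to CSV with both ordered directions", {
  d <- sample_pair(1000, seed = 5)
  st <- bootstrap_strengths(d, algorithms = "hc", B = 5, seed = 6)
  expect_equal(nrow(st), 2L)
  expect_equal(st$direction_frequency[1] + st$direction_frequency[2], 1.0)
  f <- tempfile(fileext = ".csv")
  write_strengths_csv(st, f)
  back <- read.csv(f)
  expect_equal(back$adjacency_frequency, st$adjacency_frequency)
})
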