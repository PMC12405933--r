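test_that("G2 statistic matches closed-form values", {
  # perfectly dependent 2x2 table [[10,0],[0,10]]: G2 = 40 ln 2, df 1
  d <- data.frame(x = factor(rep(c("a", "b"), each = 10)),
                  y = factor(rep(c("a", "b"), each = 10)))
  r <- g2_test("x", "y", character(0), d)
  expect_equal(r$statistic, 40 * log(2), tolerance = 1e-10)
  expect_equal(r$degrees_of_freedom, 1L)
  expect_lt(r$p_value, 1e-6)
  # perfectly uniform independent table: statistic exactly 0, p = 1
  d2 <- data.frame(x = factor(rep(c("a", "b"), 50)),
                   y = factor(rep(c("a", "a", "b", "b"), 25)))
  r2 <- g2_test("x", "y", character(0), d2)
  expect_equal(r2$statistic, 0, tolerance = 1e-12)
  expect_equal(r2$p_value, 1)
})

test_that("conditional statistic equals the sum of per-stratum statistics", {
  set.seed(8)
  n <- 2000
  z <- factor(sample(c("s1", "s2", "s3"), n, TRUE))
  x <- factor(ifelse(runif(n) < c(0.3, 0.5, 0.7)[as.integer(z)], "a", "b"))
  y <- factor(ifelse(runif(n) < c(0.6, 0.4, 0.2)[as.integer(z)], "a", "b"))
  d <- data.frame(x = x, y = y, z = z)
  cond <- g2_test("x", "y", "z", d)
  parts <- vapply(levels(z), function(l) {
    g2_test("x", "y", character(0), d[d$z == l, c("x", "y")])$statistic
  }, 1.0)
  expect_equal(cond$statistic, sum(parts), tolerance = 1e-9)
  expect_equal(cond$degrees_of_freedom, 3L)
})

test_that("continuous input and degenerate strata are handled", {
  expect_error(g2_test("x", "y", character(0),
                       data.frame(x = rnorm(10), y = rnorm(10))),
               class = "exacnet_discrete_error")
  # single-level column collapses dof; test flagged unreliable but returned
  d <- data.frame(x = factor(rep("a", 20)), y = factor(rep(c("u", "v"), 10)))
  r <- g2_test("x", "y", character(0), d)
  expect_true(r$unreliable)
  expect_equal(r$degrees_of_freedom, 1L)
  # Pearson variant agrees with stats::chisq.test
  set.seed(9)
  d2 <- data.frame(x = factor(sample(c("a", "b"), 500, TRUE)),
                   y = factor(sample(c("u", "v", "w"), 500, TRUE)))
  r2 <- g2_test("x", "y", character(0), d2, test = "x2")
  ref <- suppressWarnings(stats::chisq.test(table(d2$x, d2$y), correct = FALSE))
  expect_equal(r2$statistic, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(r2$degrees_of_freedom, unname(ref$parameter))
})
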