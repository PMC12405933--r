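test_that("zero and outlier recoding masks the configured cells", {
  d <- data.frame(bec = c(0, 250, 7000), feno = c(0, 25, 300), ige = c(5, 10, 20))
  r <- recode_zeros_and_outliers(d, rules = list(
    zero_columns = c("bec", "feno", "ige"),
    bounds = list(bec = c(0, 5000))))
  expect_true(is.na(r$feno[1]) && !is.na(r$feno[2]) && !is.na(r$feno[3]))
  expect_true(is.na(r$bec[3])) # 7000 outside (0, 5000]
  log <- attr(r, "recode_log")
  expect_equal(log$n_outlier[log$column == "bec"], 1L)
  # nothing to recode: identity with empty log
  clean <- data.frame(bec = c(100, 200), feno = c(30, 40), ige = c(10, 20))
  r2 <- recode_zeros_and_outliers(clean, rules = list(
    zero_columns = "bec", bounds = list(bec = c(0, 5000))))
  expect_identical(r2$bec, clean$bec)
  expect_equal(nrow(attr(r2, "recode_log")), 0L)
  expect_error(recode_zeros_and_outliers(clean, rules = list(zero_columns = "nope")),
               class = "exacnet_config_error")
})

test_that("fixed clinical cuts follow the half-open upward convention", {
  expect_equal(as.character(fixed_clinical_cuts(c(100, 150, 500), c(150, 300))),
               c("low", "mid", "high"))
  expect_equal(as.character(fixed_clinical_cuts(25, c(25, 50))), "mid")
  expect_equal(length(fixed_clinical_cuts(numeric(0), c(1, 2))), 0L)
  expect_error(fixed_clinical_cuts(1:3, c(5, 5)))
  # order preservation: u < v implies level(u) <= level(v)
  set.seed(1)
  v <- sort(runif(100, 0, 100))
  lev <- as.integer(fixed_clinical_cuts(v, c(30, 60)))
  expect_true(all(diff(lev) >= 0))
})

test_that("hartemink merging reaches target levels and preserves information", {
  set.seed(2)
  n <- 600
  x <- rnorm(n)
  d <- data.frame(a = x, b = x + rnorm(n, 0, 0.25), c = rnorm(n), e = rnorm(n))
  h <- discretize_hartemink(d, target_levels = 3, initial_bins = 6)
  expect_true(all(vapply(h$data, nlevels, 1L) == 3L))
  expect_equal(length(h$map$columns$a$cuts), 2L) # 6 bins - 3 merges
  # order-preserving map
  lev <- as.integer(apply_discretization(h$map, d)$a)
  expect_true(all(diff(lev[order(d$a)]) >= 0))
  # already at target levels with initial_bins = target_levels: no merging
  d2 <- data.frame(a = rep(c(1, 5, 9), each = 50), b = rnorm(150))
  h2 <- discretize_hartemink(d2, target_levels = 3, initial_bins = 3,
                             columns = "a")
  expect_equal(nlevels(h2$data$a), 3L)
  expect_equal(as.vector(table(h2$data$a)), c(50L, 50L, 50L))
  # greedy merging retains at least as much total pairwise mutual
  # information as random merging of the same variable (paired comparison)
  wins <- 0L
  for (s in 1:50) {
    set.seed(100 + s)
    x <- rnorm(300)
    dd <- data.frame(a = x, b = x + rnorm(300, 0, 0.3), c = rnorm(300))
    hh <- discretize_hartemink(dd, target_levels = 3, initial_bins = 8,
                               columns = "a")
    # evaluate the same objective the merging minimizes losses against:
    # total pairwise MI with the companions at their 8-bin quantile coding
    codes8 <- function(v) {
      qs <- unique(quantile(v, 1:7 / 8, names = FALSE))
      findInterval(v, qs) + 1L
    }
    comp <- lapply(dd[c("b", "c")], codes8)
    mi_with <- function(acode) {
      sum(vapply(comp, function(o)
        exacnet:::mi_pair(acode, max(acode), o, max(o)), 1.0))
    }
    greedy <- mi_with(as.integer(hh$data$a))
    qs <- unique(quantile(dd$a, 1:7 / 8, names = FALSE))
    code <- findInterval(dd$a, qs) + 1L
    drop <- sort(sample(seq_along(qs), length(qs) - 2))
    rnd <- findInterval(dd$a, qs[-drop]) + 1L
    if (greedy >= mi_with(rnd) - 1e-12) wins <- wins + 1L
  }
  expect_gte(wins, 48L) # >= 95% of paired runs
  # constant column warns, single level
  expect_warning(h3 <- discretize_hartemink(data.frame(a = rep(1, 50), b = rnorm(50)),
                                            columns = "a"))
  expect_equal(nlevels(h3$data$a), 1L)
  expect_error(discretize_hartemink(data.frame(a = factor(c("x", "y"))), columns = "a"))
})

test_that("discretization maps serialize and reapply identically", {
  coh <- core9_cohort(2000, seed = 51)
  disc <- discretize_clinical(coh)
  f <- tempfile(fileext = ".json")
  write_discretization_json(disc$map, f)
  map2 <- read_discretization_json(f)
  re <- apply_discretization(map2, coh)
  expect_identical(re$bec, disc$data$bec)
  expect_identical(re$age, disc$data$age)
})
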