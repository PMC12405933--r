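test_that("synthetic row counts follow the G formula exactly", {
  set.seed(1)
  f <- data.frame(a = rnorm(100), b = rnorm(100))
  lab <- factor(rep(c("maj", "min"), c(90, 10)))
  f$a[lab == "min"] <- f$a[lab == "min"] + 2
  out <- adasyn_balance(f, lab, k_neighbors = 5, target_ratio = 1, seed = 2)
  expect_equal(unname(out$n_synthetic["min"]), 80L) # (90 - 10) x 1
  expect_equal(as.vector(table(out$labels)), c(90L, 90L))
  expect_equal(nrow(out$features), 180L)
  # originals preserved as the leading rows
  expect_equal(out$features$a[1:100], f$a)
  # already balanced: nothing generated
  bal <- adasyn_balance(f, factor(rep(c("x", "y"), 50)), seed = 3)
  expect_true(all(bal$n_synthetic == 0L))
  expect_equal(nrow(bal$features), 100L)
})

test_that("three-class rebalancing reaches near-exact balance", {
  set.seed(4)
  n <- 1000
  f <- data.frame(a = rnorm(n), b = rnorm(n),
                  g = factor(sample(c("u", "v"), n, TRUE)))
  lab <- factor(rep(c("0", "1", "2+"), c(700, 200, 100)), levels = c("0", "1", "2+"))
  out <- adasyn_balance(f, lab, k_neighbors = 5, target_ratio = 1, seed = 5)
  counts <- table(out$labels)
  expect_true(all(counts[c("1", "2+")] / counts["0"] >= 0.95))
  expect_true(all(counts[c("1", "2+")] / counts["0"] <= 1.05))
})

test_that("synthetic points interpolate numerics and copy categoricals", {
  set.seed(6)
  f <- data.frame(a = rnorm(60), g = factor(sample(c("p", "q"), 60, TRUE)))
  lab <- factor(rep(c("maj", "min"), c(45, 15)))
  out <- adasyn_balance(f, lab, k_neighbors = 5, seed = 7)
  syn <- out$features[-(1:60), , drop = FALSE]
  min_rows <- f[lab == "min", ]
  # every synthetic numeric lies within the minority class's coordinate range
  # (interpolation between a seed and a minority neighbour cannot escape it)
  expect_true(all(syn$a >= min(min_rows$a) - 1e-12 &
                    syn$a <= max(min_rows$a) + 1e-12))
  # categorical values are copied from minority seeds
  expect_true(all(as.character(syn$g) %in% as.character(min_rows$g)))
})

test_that("degenerate inputs are refused", {
  f <- data.frame(a = rnorm(20))
  expect_error(adasyn_balance(f, factor(rep("one", 20)), seed = 1))
  lab <- factor(rep(c("maj", "min"), c(17, 3)))
  expect_error(adasyn_balance(f, lab, k_neighbors = 5, seed = 1))
  f$a[1] <- NA
  expect_error(adasyn_balance(f, factor(rep(c("x", "y"), 10)), seed = 1))
})
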