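test_that("fold plans partition the cohort as specified", {
  coh <- core9_cohort(100, seed = 120)
  plan <- make_folds(coh, "kfold", k = 10, seed = 1)
  expect_equal(as.vector(table(plan$fold)), rep(10L, 10))
  # stratified: per-fold class counts within one patient of proportionality
  coh2 <- core9_cohort(1000, seed = 121)
  coh2$future_exac <- factor(rep(c("0", "1", "2+"), c(700, 200, 100)),
                             levels = c("0", "1", "2+"))
  plan2 <- make_folds(coh2, "kfold", k = 10, seed = 2)
  tab <- table(plan2$fold, coh2$future_exac)
  expect_true(all(abs(tab - rep(c(70, 20, 10), each = 10)) <= 1))
  # leave-one-country-out: folds are exactly the country partition
  coh2$country <- factor(rep(c("A", "B", "C"), length.out = 1000))
  loco <- make_folds(coh2, "loco")
  expect_equal(loco$k, 3L)
  expect_true(all(tapply(as.integer(coh2$country), loco$fold,
                         function(v) length(unique(v))) == 1L))
  coh2$country <- factor(rep("A", 1000))
  expect_error(make_folds(coh2, "loco"))
})

test_that("AUC equals the concordant-pair oracle, with tie convention", {
  # worked example: positives (.9, .8, .2), negative (.4) -> AUC 2/3
  pr <- data.frame(p_0 = 1 - c(0.9, 0.8, 0.2, 0.4), p_1 = c(0.9, 0.8, 0.2, 0.4) / 2,
                   `p_2+` = c(0.9, 0.8, 0.2, 0.4) / 2, check.names = FALSE)
  pr$p_ge1 <- c(0.9, 0.8, 0.2, 0.4)
  pr$p_ge2 <- pr$p_ge1 / 2
  oc <- factor(c("1", "1", "1", "0"), levels = c("0", "1", "2+"))
  m <- classification_metrics(pr, oc, "ge1")
  expect_equal(m$auc, 2 / 3, tolerance = 1e-12)
  # random scores against the pair-counting oracle and pROC
  withr::with_seed(3, {
    n <- 200
    y <- rbinom(n, 1, 0.3)
    s <- round(runif(n), 2) # rounded scores force ties
    prr <- data.frame(p_0 = 1 - s, p_1 = s * 0.6, `p_2+` = s * 0.4,
                      check.names = FALSE)
    prr$p_ge1 <- s
    prr$p_ge2 <- s * 0.4
    occ <- factor(ifelse(y == 1, "1", "0"), levels = c("0", "1", "2+"))
    mine <- classification_metrics(prr, occ, "ge1")$auc
    expect_equal(mine, auc_pair_oracle(s, y), tolerance = 1e-12)
    if (requireNamespace("pROC", quietly = TRUE)) {
      ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE, direction = "<")))
      expect_equal(mine, ref, tolerance = 1e-9)
    }
  })
  # perfect separation and all-tied scores
  prp <- data.frame(p_0 = c(0.1, 0.9), p_1 = c(0.9, 0.1), `p_2+` = c(0, 0),
                    check.names = FALSE)
  prp$p_ge1 <- c(0.9, 0.1); prp$p_ge2 <- c(0, 0)
  ocp <- factor(c("1", "0"), levels = c("0", "1", "2+"))
  mp <- classification_metrics(prp, ocp, "ge1")
  expect_equal(mp$auc, 1)
  expect_equal(mp$accuracy, 1)
  prt <- prp; prt$p_ge1 <- c(0.5, 0.5)
  expect_equal(classification_metrics(prt, ocp, "ge1")$auc, 0.5)
  # single-class outcome: flagged undefined
  expect_equal(classification_metrics(prp, factor(c("0", "0"), levels = c("0", "1", "2+")),
                                      "ge1")$flag, "undefined")
})

test_that("calibration recovers slope 1 under self-consistency and 2 under halving", {
  withr::with_seed(4, {
    p <- runif(50000, 0.02, 0.6)
    y <- rbinom(50000, 1, p)
  })
  cm <- calibration_metrics(p, y)
  expect_true(cm$slope > 0.95 && cm$slope < 1.05)
  expect_true(abs(cm$intercept) < 0.05)
  # halving all predicted logits doubles the recovered slope
  cm2 <- calibration_metrics(stats::plogis(stats::qlogis(p) / 2), y)
  expect_equal(cm2$slope, 2, tolerance = 0.1)
  # constant predictions: flagged degenerate
  expect_equal(calibration_metrics(rep(0.3, 100), rbinom(100, 1, 0.3))$flag,
               "degenerate")
  # out-of-range probabilities are clipped with a warning
  expect_warning(calibration_metrics(c(0, 0.5, 1), c(0, 1, 1)))
})

test_that("cross-validation is deterministic and leak-free", {
  coh <- core9_cohort(1200, seed = 130)
  cfg <- pipeline_config(rebalance = FALSE)
  plan <- make_folds(coh, "kfold", k = 3, seed = 5)
  r1 <- cross_validate(coh, cfg, plan, seed = 6)
  r2 <- cross_validate(coh, cfg, plan, seed = 6)
  expect_identical(r1$per_fold, r2$per_fold)
  expect_identical(r1$predictions, r2$predictions)
  expect_equal(nrow(r1$predictions), 1200L)
  expect_true(all(r1$per_fold$n == 400L))
  # report serializes
  f <- tempfile(fileext = ".json")
  write_validation_json(r1, f)
  expect_true(jsonlite::validate(readChar(f, file.size(f))))
})

test_that("train-test split stratifies and guards tiny test sets", {
  coh <- core9_cohort(1000, seed = 131)
  sr <- train_test_split_report(coh, 0.7, pipeline_config(rebalance = FALSE),
                                seed = 7)
  expect_equal(sr$n_train + sr$n_test, 1000L)
  expect_true(abs(sr$n_train - 700) <= 2)
  expect_equal(sr$flag, "ok")
  sr2 <- train_test_split_report(coh, 0.99, pipeline_config(rebalance = FALSE),
                                 seed = 8)
  expect_equal(sr2$flag, "unstable")
})
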