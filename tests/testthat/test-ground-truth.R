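test_that("core9 preset reproduces the registry's baseline marginals", {
  spec <- core9_spec()
  expect_equal(length(spec$nodes), 10L) # 9 pathway variables + country
  g <- attr(validate_ground_truth(spec), "graph")
  a <- apply(arcs(g), 1, paste, collapse = ">")
  expect_true(all(c("crs>bec", "fev1pp>feno", "bec>feno", "prior_exac>future_exac",
                    "age>crs", "sex>crs", "age>macrolide", "macrolide>future_exac")
                  %in% a))
  expect_equal(unname(spec$nodes$sex$cpt[2, 1]), 0.612)
  crs_marg <- exacnet:::parent_config_probs(spec, "crs")
  expect_equal(crs_marg, c(0.489, 0.200, 0.311), tolerance = 1e-6)
  mac_marg <- exacnet:::parent_config_probs(spec, "macrolide")
  expect_equal(mac_marg[2], 0.119, tolerance = 1e-6)
  # every conditional table column sums to one
  for (nd in spec$nodes) expect_true(all(abs(colSums(nd$cpt) - 1) < 1e-12))
})

test_that("sampling matches the spec's forward-computed marginals", {
  coh <- core9_cohort(50000, seed = 1)
  expect_equal(mean(coh$sex == "Female"), 0.612, tolerance = 0.01)
  expect_true(all(coh$age >= 18))
  expect_true(all(coh$bec >= 0) && all(coh$feno >= 0) && all(coh$ige >= 0))
  expect_true(all(coh$fev1pp > 0 & coh$fev1pp < 200))
  expect_true(all(levels(coh$future_exac) == c("0", "1", "2+")))
  # determinism contract
  expect_identical(sample_cohort(core9_spec(), 200, seed = 7),
                   sample_cohort(core9_spec(), 200, seed = 7))
})

test_that("empirical conditionals factorize over the spec's DAG", {
  # P(X | parents) at large n matches the spec's band-level table per cell
  spec <- core9_spec()
  coh <- core9_cohort(100000, seed = 3)
  bands <- attr(coh, "bands")
  for (nm in c("crs", "bec", "feno", "future_exac")) {
    nd <- spec$nodes[[nm]]
    nlev <- vapply(spec$nodes, function(x) length(x$levels), 1L)
    cfg <- exacnet:::cfg_index_codes(bands[, nd$parents, drop = FALSE],
                                     unname(nlev[nd$parents]))
    for (k in unique(cfg)) {
      rows <- cfg == k
      if (sum(rows) < 5000) next
      emp <- tabulate(bands[rows, nm], nbins = length(nd$levels)) / sum(rows)
      expect_true(max(abs(emp - nd$cpt[, k])) < 0.02)
    }
  }
})

test_that("degenerate and invalid specs are rejected or honoured", {
  spec <- core9_spec()
  # point mass: everyone female
  spec2 <- spec
  spec2$nodes$sex$cpt <- matrix(c(0, 1))
  spec2 <- validate_ground_truth(spec2)
  coh <- sample_cohort(spec2, 500, seed = 1)
  expect_true(all(coh$sex == "Female"))
  # cyclic custom arc set
  n1 <- exacnet:::gt_node_discrete("A", c("x", "y"), parents = "B",
                                   cpt = matrix(0.5, 2, 2))
  n2 <- exacnet:::gt_node_discrete("B", c("x", "y"), parents = "A",
                                   cpt = matrix(0.5, 2, 2))
  expect_error(make_ground_truth_network("custom", nodes = list(n1, n2)),
               class = "exacnet_cycle_error")
  # CPT column not summing to one
  spec3 <- spec
  spec3$nodes$sex$cpt <- matrix(c(0.5, 0.6))
  expect_error(validate_ground_truth(spec3), class = "exacnet_validation_error")
})

test_that("missingness injection hits configured rates and mechanisms", {
  coh <- core9_cohort(10000, seed = 21)
  # 20% MCAR on bec: realized fraction within the binomial 99% interval
  plan <- list(list(column = "bec", rate = 0.2, mechanism = "MCAR"))
  out <- inject_missingness(coh, plan, seed = 4)
  expect_true(mean(is.na(out$bec)) > 0.19 && mean(is.na(out$bec)) < 0.21)
  expect_false(anyNA(out$future_exac))
  # rate 0: identity
  out0 <- inject_missingness(coh, list(list(column = "bec", rate = 0)), seed = 4)
  expect_identical(out0$bec, coh$bec)
  # MAR(feno | crs): per-stratum odds follow the configuration
  plan2 <- list(list(column = "feno", rate = 0.15, mechanism = "MAR",
                     driver = "crs", odds = c(None = 1, CRSwoNP = 0.5, CRSwNP = 0.25)))
  out2 <- inject_missingness(coh, plan2, seed = 5)
  r <- tapply(is.na(out2$feno), coh$crs, mean)
  odds <- function(p) p / (1 - p)
  expect_equal(unname(odds(r["CRSwoNP"]) / odds(r["None"])), 0.5, tolerance = 0.25)
  expect_true(r["None"] > r["CRSwNP"])
  # MAR driver itself targeted: configuration error
  bad <- list(list(column = "crs", rate = 0.1),
              list(column = "feno", rate = 0.1, mechanism = "MAR",
                   driver = "crs", odds = c(None = 1, CRSwoNP = 1, CRSwNP = 1)))
  expect_error(inject_missingness(coh, bad, seed = 1),
               class = "exacnet_config_error")
})

test_that("country assignment labels patients and shifts outcome rates", {
  spec <- core9_spec()
  coh <- core9_cohort(20000, seed = 31)
  out2 <- assign_country(coh, spec, k_countries = 2, effect_sd = 0, seed = 8)
  expect_equal(nlevels(droplevels(out2$country)), 2L)
  # with effect_sd > 0 the between-country spread of observed rates exceeds
  # the no-effect case
  rate_spread <- function(effect_sd, seed) {
    cc <- assign_country(coh, spec, 10, effect_sd, seed)
    sd(tapply(cc$future_exac != "0", cc$country, mean))
  }
  s0 <- mean(vapply(1:3, function(s) rate_spread(0, s), 1.0))
  s3 <- mean(vapply(1:3, function(s) rate_spread(0.5, s), 1.0))
  expect_gt(s3, s0)
})

test_that("spec JSON round-trips and the true discrete net is exact", {
  spec <- core9_spec()
  f <- tempfile(fileext = ".json")
  write_ground_truth_json(spec, f)
  spec2 <- read_ground_truth_json(f)
  expect_equal(names(spec2$nodes), names(spec$nodes))
  expect_equal(spec2$nodes$future_exac$cpt, spec$nodes$future_exac$cpt,
               tolerance = 1e-12)
  # counterfactual monotonicity built into the defaults
  net <- true_discrete_net(spec)
  cc <- counterfactual_compare(net, "crs", c("None", "CRSwoNP", "CRSwNP"),
                               "future_exac")
  expect_true(all(diff(cc$p_ge1) > 0))
  # cohort CSV round trip with missing cells as empty fields
  coh <- inject_missingness(core9_cohort(500, seed = 41), spec, seed = 2)
  f2 <- tempfile(fileext = ".csv")
  write_cohort_csv(coh, f2)
  back <- read_cohort_csv(f2)
  expect_equal(nrow(back), 500)
  expect_equal(mean(is.na(back$feno)), mean(is.na(coh$feno)))
  expect_equal(levels(back$crs), c("None", "CRSwoNP", "CRSwNP"))
})
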