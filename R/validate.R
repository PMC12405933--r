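# Internal-external validation: k-fold and leave-one-country-out
# cross-validation with discrimination, confusion and calibration metrics.

#' Build a cross-validation fold plan
#'
#' `kfold` folds are stratified by outcome level and differ in size by at
#' most one; `loco` (leave-one-country-out) folds are the country partition.
#'
#' @param cohort Cohort data frame.
#' @param scheme `"kfold"` or `"loco"`.
#' @param k Number of folds for `kfold` (default 10).
#' @param seed Integer seed (used by `kfold` shuffling).
#' @param outcome Outcome column (stratification variable).
#' @return A `fold_plan`: integer fold id per patient plus scheme metadata.
#' @export
make_folds <- function(cohort, scheme = c("kfold", "loco"), k = 10L, seed = 1L,
                       outcome = "future_exac") {
  scheme <- match.arg(scheme)
  n <- nrow(cohort)
  if (scheme == "kfold") {
    y <- cohort[[outcome]]
    ord <- withr::with_seed(seed, {
      idx <- sample.int(n)       # shuffle, then group by class
      idx[order(as.integer(y)[idx])]
    })
    fold <- integer(n)
    fold[ord] <- rep(seq_len(k), length.out = n)
    labels <- as.character(seq_len(k))
  } else {
    ctry <- cohort$country
    if (is.null(ctry) || length(unique(ctry)) < 2L) {
      stop2("leave-one-country-out requires a country column with >= 2 countries")
    }
    f <- factor(ctry)
    fold <- as.integer(f)
    labels <- levels(f)
    k <- nlevels(f)
  }
  structure(list(fold = fold, scheme = scheme, k = k, seed = seed,
                 labels = labels),
            class = "fold_plan")
}

#' Discrimination and confusion metrics at a risk cut
#'
#' AUC is the probability that a random positive outranks a random negative
#' (ties count one half; the normalized Mann-Whitney statistic). Confusion
#' metrics assign each patient the maximum-probability outcome class and
#' collapse it at the cut.
#'
#' @param predictions Data frame from [predict_exacerbation_risk()] (needs
#'   `p_ge1`, `p_ge2` and the per-level columns).
#' @param outcomes Observed outcome factor (levels 0 / 1 / 2+).
#' @param cut `"ge1"` or `"ge2"`.
#' @return List: `auc`, `specificity`, `precision`, `recall`, `accuracy`,
#'   and `flag` (`"undefined"` when the outcome is single-class).
#' @export
classification_metrics <- function(predictions, outcomes, cut = c("ge1", "ge2")) {
  cut <- match.arg(cut)
  lv <- levels(outcomes)
  y <- if (cut == "ge1") as.integer(outcomes != lv[1]) else
    as.integer(outcomes == lv[length(lv)])
  score <- predictions[[paste0("p_", cut)]]
  if (length(unique(y)) < 2L) {
    return(list(auc = NA_real_, specificity = NA_real_, precision = NA_real_,
                recall = NA_real_, accuracy = NA_real_, flag = "undefined"))
  }
  r <- rank(score) # midranks: ties count 1/2
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  pcols <- paste0("p_", lv)
  cls <- max.col(as.matrix(predictions[pcols]), ties.method = "first")
  yhat <- if (cut == "ge1") as.integer(cls > 1L) else as.integer(cls == length(lv))
  tp <- sum(yhat == 1 & y == 1); tn <- sum(yhat == 0 & y == 0)
  fp <- sum(yhat == 1 & y == 0); fn <- sum(yhat == 0 & y == 1)
  list(auc = auc,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       accuracy = (tp + tn) / length(y),
       flag = "ok")
}

#' Calibration slope and intercept
#'
#' Logistic recalibration of the binary outcome on the logit of the
#' predicted probability: the slope comes from the full recalibration model,
#' the intercept from the offset model with slope fixed at 1
#' (calibration-in-the-large). A slope near 1 and intercept near 0 indicate
#' good calibration. Probabilities at 0/1 are clipped to `[1e-6, 1 - 1e-6]`
#' with a warning.
#'
#' @param predicted_probabilities Numeric vector in (0, 1).
#' @param binary_outcomes 0/1 vector.
#' @return List: `intercept`, `slope`, `flag` (`"degenerate"` when the
#'   logits have no variance).
#' @export
calibration_metrics <- function(predicted_probabilities, binary_outcomes) {
  p <- predicted_probabilities
  y <- as.integer(binary_outcomes)
  stopifnot(length(p) == length(y), all(y %in% 0:1))
  if (any(p <= 0 | p >= 1)) {
    warning("probabilities at 0/1 clipped to [1e-6, 1 - 1e-6]")
    p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  }
  lp <- stats::qlogis(p)
  if (sd(lp) < 1e-12) {
    return(list(intercept = NA_real_, slope = NA_real_, flag = "degenerate"))
  }
  ctrl <- stats::glm.control(epsilon = 1e-10, maxit = 100)
  slope <- unname(coef(suppressWarnings(
    glm(y ~ lp, family = binomial(), control = ctrl)))[2])
  intercept <- unname(coef(suppressWarnings(
    glm(y ~ 1 + offset(lp), family = binomial(), control = ctrl)))[1])
  list(intercept = intercept, slope = slope, flag = "ok")
}

# ---- pipeline model fitting (train folds only) -----------------------------

#' Default pipeline configuration for model fitting and validation
#'
#' @param outcome Outcome node (default `"future_exac"`).
#' @param predictors Predictor columns (default: the core pathway
#'   predictors).
#' @param discretization `"clinical"` (fixed threshold bands) or
#'   `"hartemink"`.
#' @param rebalance Apply ADASYN to training folds (default `TRUE`; test
#'   folds are never rebalanced).
#' @param learner Structure learner for per-fold fitting: `"hc"`, `"tabu"`,
#'   or `"consensus"` (bootstrap averaging; slower), or `"true"` to use a
#'   fixed arc set supplied in `arcs`.
#' @param B,threshold Consensus parameters when `learner = "consensus"`.
#' @param arcs Fixed arc matrix when `learner = "true"`.
#' @param smoothing_alpha CPT smoothing (default 1).
#' @param k_neighbors ADASYN neighbourhood size.
#' @param constraints Optional `expert_constraints`.
#' @return A named list (class `pipeline_config`).
#' @export
pipeline_config <- function(outcome = "future_exac",
                            predictors = c("age", "sex", "crs", "macrolide", "bec",
                                           "feno", "fev1pp", "prior_exac"),
                            discretization = "clinical", rebalance = TRUE,
                            learner = "hc", B = 200L, threshold = 0.75,
                            arcs = NULL, smoothing_alpha = 1, k_neighbors = 5L,
                            constraints = NULL) {
  structure(list(outcome = outcome, predictors = predictors,
                 discretization = discretization, rebalance = rebalance,
                 learner = learner, B = B, threshold = threshold, arcs = arcs,
                 smoothing_alpha = smoothing_alpha, k_neighbors = k_neighbors,
                 constraints = constraints),
            class = "pipeline_config")
}

# fit the full preprocessing + structure + CPT pipeline on training data
fit_pipeline_model <- function(train, config, seed = 1L) {
  cols <- c(config$predictors, config$outcome)
  train <- train[cols]
  disc <- if (identical(config$discretization, "hartemink")) {
    discretize_hartemink(train)
  } else {
    discretize_clinical(train)
  }
  dtrain <- disc$data
  if (isTRUE(config$rebalance)) {
    bal <- adasyn_balance(dtrain[config$predictors], dtrain[[config$outcome]],
                          k_neighbors = config$k_neighbors,
                          seed = derive_seed(seed, "adasyn"))
    dtrain <- bal$features
    dtrain[[config$outcome]] <- bal$labels
  }
  wl <- config$constraints$whitelist
  bl <- config$constraints$blacklist
  dag <- switch(config$learner,
    hc   = hill_climb(dtrain, whitelist = wl, blacklist = bl),
    tabu = hill_climb(dtrain, tabu_length = 10, whitelist = wl, blacklist = bl),
    consensus = {
      st <- bootstrap_strengths(dtrain, B = config$B,
                                constraints = config$constraints,
                                seed = derive_seed(seed, "consensus"))
      pdag_to_dag(averaged_network(st, config$threshold))
    },
    true = bn_graph(names(dtrain), arcs = config$arcs),
    stop2("unknown learner '%s'", config$learner))
  net <- fit_cpts(dag, dtrain, smoothing_alpha = config$smoothing_alpha)
  list(net = net, map = disc$map, config = config)
}

predict_pipeline_model <- function(model, test) {
  dtest <- apply_discretization(model$map, test)
  predict_exacerbation_risk(model$net, dtest[model$config$predictors],
                            outcome = model$config$outcome)
}

#' Cross-validate the pathway pipeline
#'
#' For every fold, the entire pipeline — discretization-map fitting,
#' optional ADASYN rebalancing, structure learning and CPT estimation — runs
#' on the training portion only; the fitted network predicts the held-out
#' patients at their natural prevalence. Discrimination and confusion
#' metrics are reported per fold and pooled over all held-out predictions.
#'
#' @param cohort Cohort data frame (no missing values in the modelled
#'   columns).
#' @param config A [pipeline_config()].
#' @param fold_plan A [make_folds()] plan.
#' @param seed Integer seed (per-fold seeds derive from it).
#' @return A `validation_report`: `per_fold`, `pooled`, `predictions`,
#'   `fold_plan`, `config`.
#' @export
cross_validate <- function(cohort, config, fold_plan, seed = 1L) {
  stopifnot(inherits(fold_plan, "fold_plan"))
  outcome <- config$outcome
  preds_all <- vector("list", fold_plan$k)
  per_fold <- list()
  for (f in seq_len(fold_plan$k)) {
    test_idx <- which(fold_plan$fold == f)
    if (!length(test_idx)) next
    train <- cohort[-test_idx, , drop = FALSE]
    test <- cohort[test_idx, , drop = FALSE]
    test_checksum <- serialize_checksum(test)
    model <- fit_pipeline_model(train, config, seed = derive_seed(seed, paste0("fold", f)))
    pr <- predict_pipeline_model(model, test)
    stopifnot(identical(serialize_checksum(test), test_checksum)) # no leakage
    pr$fold <- f
    pr$outcome <- test[[outcome]]
    pr$patient_id <- test$patient_id %||% test_idx
    preds_all[[f]] <- pr
    row <- list(fold = f, n = nrow(test))
    for (cut in c("ge1", "ge2")) {
      m <- classification_metrics(pr, test[[outcome]], cut)
      for (nm in c("auc", "specificity", "precision", "recall", "accuracy")) {
        row[[paste0(nm, "_", cut)]] <- m[[nm]]
      }
      row[[paste0("flag_", cut)]] <- m$flag
    }
    per_fold[[length(per_fold) + 1L]] <- as.data.frame(row)
  }
  predictions <- do.call(rbind, preds_all)
  pooled <- list()
  for (cut in c("ge1", "ge2")) {
    pooled[[cut]] <- classification_metrics(predictions, predictions$outcome, cut)
  }
  pooled$auc_macro <- mean(c(pooled$ge1$auc, pooled$ge2$auc))
  structure(list(scheme = fold_plan$scheme, per_fold = do.call(rbind, per_fold),
                 pooled = pooled, predictions = predictions,
                 fold_plan = fold_plan, config = config, seed = seed),
            class = "validation_report")
}

serialize_checksum <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f)
  unname(tools::md5sum(f))
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Validation report (%s): pooled AUC >=1: %.3f, >=2: %.3f, macro: %.3f\n",
              x$scheme, x$pooled$ge1$auc, x$pooled$ge2$auc, x$pooled$auc_macro))
  invisible(x)
}

#' Single stratified train-test split with calibration
#'
#' Fits the pipeline on a stratified `fraction` of the cohort (or scores a
#' supplied network) and reports discrimination plus calibration slope and
#' intercept for both risk cuts on the held-out portion.
#'
#' @param cohort Cohort data frame.
#' @param fraction Training fraction in (0, 1), default 0.70.
#' @param config A [pipeline_config()].
#' @param seed Integer seed.
#' @param net Optional fitted `exacnet_dbn` to score instead of fitting on
#'   the training portion (the training rows are then unused); evidence is
#'   discretized with the default clinical map.
#' @return A `split_report` list: `n_train`, `n_test`, `metrics` (per cut),
#'   `calibration` (per cut), `flag` (`"unstable"` for tiny test sets).
#' @export
train_test_split_report <- function(cohort, fraction = 0.70, config = pipeline_config(),
                                    seed = 1L, net = NULL) {
  stopifnot(fraction > 0, fraction < 1)
  outcome <- config$outcome
  y <- cohort[[outcome]]
  n <- nrow(cohort)
  train_idx <- withr::with_seed(derive_seed(seed, "split"), {
    unlist(lapply(levels(y), function(l) {
      ids <- which(y == l)
      sample(ids, round(length(ids) * fraction))
    }))
  })
  test <- cohort[-train_idx, , drop = FALSE]
  train <- cohort[train_idx, , drop = FALSE]
  if (is.null(net)) {
    model <- fit_pipeline_model(train, config, seed = derive_seed(seed, "fit"))
  } else {
    model <- list(net = net, map = discretize_clinical(train)$map, config = config)
  }
  pr <- predict_pipeline_model(model, test)
  pr$outcome <- test[[outcome]]
  lv <- levels(y)
  metrics <- calib <- list()
  for (cut in c("ge1", "ge2")) {
    metrics[[cut]] <- classification_metrics(pr, test[[outcome]], cut)
    yb <- if (cut == "ge1") as.integer(test[[outcome]] != lv[1]) else
      as.integer(test[[outcome]] == lv[length(lv)])
    calib[[cut]] <- calibration_metrics(pr[[paste0("p_", cut)]], yb)
  }
  structure(list(n_train = nrow(train), n_test = nrow(test), metrics = metrics,
                 calibration = calib, predictions = pr, config = config,
                 flag = if (nrow(test) < 50) "unstable" else "ok"),
            class = "split_report")
}

#' @export
print.split_report <- function(x, ...) {
  cat(sprintf("70:30-style split report (train %d / test %d)%s\n", x$n_train, x$n_test,
              if (x$flag != "ok") paste0(" [", x$flag, "]") else ""))
  for (cut in names(x$calibration)) {
    cat(sprintf("  %s: AUC %.3f, calibration slope %.3f, intercept %+.3f\n",
                cut, x$metrics[[cut]]$auc, x$calibration[[cut]]$slope,
                x$calibration[[cut]]$intercept))
  }
  invisible(x)
}

#' Serialize a validation report to JSON
#' @param report A `validation_report` or `split_report`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_validation_json <- function(report, path) {
  x <- unclass(report)
  x$predictions <- NULL
  x$fold_plan <- if (!is.null(x$fold_plan)) {
    list(scheme = x$fold_plan$scheme, k = x$fold_plan$k, seed = x$fold_plan$seed)
  }
  x$config <- unclass(x$config)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  invisible(path)
}
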