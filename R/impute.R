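# Iterative nonparametric imputation with a pluggable base learner
# (missForest-style loop: impute columns in order of increasing missingness,
# stop when the between-iteration difference statistic first increases).

#' Default random-forest base learner
#'
#' Fit/predict contract used by [impute_iterative_forest()]: a function of
#' `(x_train, y_train, x_new)` returning predictions for `x_new`
#' (class labels for factor `y_train`, numeric otherwise). This default
#' wraps a 100-tree ranger forest.
#'
#' @param x_train,x_new Data frames of predictors (no missing values).
#' @param y_train Response vector (factor or numeric).
#' @return Predictions for `x_new`.
#' @export
ranger_base_learner <- function(x_train, y_train, x_new) {
  df <- x_train
  df$.response <- y_train
  fit <- ranger::ranger(dependent.variable.name = ".response", data = df,
                        num.trees = 100, respect.unordered.factors = "order",
                        num.threads = 1, verbose = FALSE)
  predict(fit, data = x_new, num.threads = 1, verbose = FALSE)$predictions
}

#' Iterative random-forest imputation
#'
#' Imputes missing predictor values by iterating a regression/classification
#' base learner over the incomplete columns, in order of increasing
#' missingness (ties broken lexicographically). The loop stops the first
#' time the difference statistic between successive imputations (computed
#' separately for continuous and categorical columns) increases, returning
#' the previous iteration's values, or at `max_iter`. Observed cells are
#' never altered. Columns with more than 50\% missing values are refused.
#'
#' @param cohort Data frame with missing cells.
#' @param max_iter Maximum sweeps (default 10).
#' @param base_learner A `function(x_train, y_train, x_new)`; default
#'   [ranger_base_learner()].
#' @param seed Integer seed (forest fitting is stochastic).
#' @param exclude Columns never imputed nor used as predictors (default
#'   `"patient_id"`).
#' @return List of class `imputation_result`: `data` (completed cohort),
#'   `iterations`, and `trace` (per-iteration difference statistics).
#' @export
impute_iterative_forest <- function(cohort, max_iter = 10L, base_learner = NULL,
                                    seed = 1L, exclude = "patient_id") {
  base_learner <- base_learner %||% ranger_base_learner
  work_cols <- setdiff(names(cohort), exclude)
  miss_frac <- vapply(cohort[work_cols], function(x) mean(is.na(x)), 1.0)
  over <- names(miss_frac)[miss_frac > 0.5]
  if (length(over)) {
    stop2("column(s) with > 50%% missing values refused: %s",
          paste(over, collapse = ", "), class = "exacnet_missingness_error")
  }
  targets <- names(miss_frac)[miss_frac > 0]
  if (!length(targets)) {
    return(structure(list(data = cohort, iterations = 0L,
                          trace = data.frame(iteration = integer(0),
                                             diff_continuous = numeric(0),
                                             diff_categorical = numeric(0))),
                     class = "imputation_result"))
  }
  targets <- targets[order(miss_frac[targets], targets)]
  na_mask <- lapply(cohort[targets], is.na)
  is_cont <- vapply(cohort[targets], is.numeric, TRUE)

  cur <- cohort
  # initial fill: mean / mode
  for (cn in targets) {
    v <- cur[[cn]]
    if (is.numeric(v)) v[is.na(v)] <- mean(v, na.rm = TRUE)
    else {
      v[is.na(v)] <- stat_mode(v[!is.na(v)])
    }
    cur[[cn]] <- v
  }
  trace <- list()
  prev_stat <- c(Inf, Inf)
  result <- cur
  iterations <- 0L
  withr::with_seed(seed, {
    for (it in seq_len(max_iter)) {
      old <- cur
      for (cn in targets) {
        mask <- na_mask[[cn]]
        preds <- setdiff(work_cols, cn)
        x_all <- cur[preds]
        yhat <- base_learner(x_all[!mask, , drop = FALSE], cohort[[cn]][!mask],
                             x_all[mask, , drop = FALSE])
        if (is.factor(cur[[cn]]) && !is.factor(yhat)) {
          yhat <- factor(as.character(yhat), levels = levels(cur[[cn]]))
        }
        cur[[cn]][mask] <- yhat
      }
      # missForest difference statistics over the imputed cells
      dc <- 0; dn <- 0; nc <- 0; nn <- 0
      for (cn in targets) {
        mask <- na_mask[[cn]]
        if (is_cont[[cn]]) {
          dn <- dn + sum((cur[[cn]][mask] - old[[cn]][mask])^2)
          nn <- nn + sum(cur[[cn]][mask]^2)
        } else {
          dc <- dc + sum(cur[[cn]][mask] != old[[cn]][mask])
          nc <- nc + sum(mask)
        }
      }
      stat <- c(if (nn > 0) dn / nn else 0, if (nc > 0) dc / nc else 0)
      trace[[it]] <- data.frame(iteration = it, diff_continuous = stat[1],
                                diff_categorical = stat[2])
      increased <- (nn > 0 && stat[1] > prev_stat[1]) ||
        (nc > 0 && stat[2] > prev_stat[2])
      if (it > 1L && increased) break # keep previous iteration's values
      result <- cur
      iterations <- it
      prev_stat <- stat
    }
  })
  # observed cells are untouched by construction; assert the invariant
  for (cn in targets) {
    obs <- !na_mask[[cn]]
    stopifnot(identical(as.character(result[[cn]][obs]),
                        as.character(cohort[[cn]][obs])) ||
                isTRUE(all.equal(result[[cn]][obs], cohort[[cn]][obs])))
  }
  structure(list(data = result, iterations = iterations,
                 trace = do.call(rbind, trace)),
            class = "imputation_result")
}

#' @export
print.imputation_result <- function(x, ...) {
  cat(sprintf("Imputation result: %d iteration(s)\n", x$iterations))
  if (nrow(x$trace)) print(x$trace, row.names = FALSE)
  invisible(x)
}
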