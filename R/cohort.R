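# Synthetic cohort sampling from a ground-truth pathway spec.

rtnorm_vec <- function(n, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd); phi <- pnorm(hi, mean, sd)
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

# band code of a value vector under a node's cuts (1-based, upward boundary:
# value == cut falls in the upper band)
band_code <- function(values, cuts) findInterval(values, cuts, left.open = FALSE) + 1L

# independent baseline columns present in every cohort but outside the core
# pathway network (marginals follow the registry's baseline table)
extra_column_samplers <- function() {
  list(
    ige = function(n) rlnorm(n, log(406.7) - 1.32^2 / 2, 1.32),
    fev1_reversibility = function(n) rtnorm_vec(n, 5.5, 9.1, 0, 60),
    er_visits = function(n) {
      cnt <- rnbinom(n, size = 0.30, mu = 0.2)
      factor(c("0", "1", "2+")[pmin(cnt, 2L) + 1L], levels = c("0", "1", "2+"))
    },
    invasive_ventilation = function(n) factor(ifelse(runif(n) < 0.010, "Yes", "No"),
                                              levels = c("No", "Yes")),
    lama = function(n) factor(ifelse(runif(n) < 0.083, "Yes", "No"), levels = c("No", "Yes")),
    anxiety = function(n) factor(ifelse(runif(n) < 0.074, "Yes", "No"), levels = c("No", "Yes")),
    eczema = function(n) factor(ifelse(runif(n) < 0.141, "Yes", "No"), levels = c("No", "Yes"))
  )
}

cohort_column_order <- function() {
  c("patient_id", "age", "sex", "crs", "bec", "feno", "fev1pp", "ige",
    "fev1_reversibility", "er_visits", "invasive_ventilation", "lama",
    "macrolide", "anxiety", "eczema", "prior_exac", "country", "future_exac")
}

#' Sample a synthetic severe-asthma cohort
#'
#' Ancestral sampling from a ground-truth pathway spec: nodes are drawn in
#' topological order, parents before children; continuous nodes draw their
#' measurement from the band-shifted distribution, exacerbation nodes draw a
#' latent negative-binomial 12-month count collapsed to 0 / 1 / 2+.
#' For the built-in presets, baseline columns outside the pathway network
#' (e.g. IgE or eczema in `core9`) are filled from independent
#' registry-calibrated marginals so the full cohort table is always present.
#' Fully reproducible given `(spec, n, seed)`.
#'
#' @param spec A `ground_truth_spec`.
#' @param n Number of patients (>= 1).
#' @param seed Integer seed.
#' @return A data frame cohort; attribute `"bands"` holds the banded integer
#'   codes of the pathway columns (useful for oracle checks).
#' @export
sample_cohort <- function(spec, n, seed) {
  stopifnot(n >= 1)
  spec <- validate_ground_truth(spec)
  g <- attr(spec, "graph")
  ord <- topo_sort(g)
  withr::with_seed(seed, {
    values <- list()
    bands <- list()
    nlev <- vapply(spec$nodes, function(nd) length(nd$levels), 1L)
    for (nm in ord) {
      nd <- spec$nodes[[nm]]
      if (length(nd$parents)) {
        codes <- vapply(nd$parents, function(p) bands[[p]], integer(n))
        if (n == 1L) codes <- matrix(codes, nrow = 1L)
        cfg <- cfg_index_codes(codes, unname(nlev[nd$parents]))
      } else cfg <- rep(1L, n)
      if (nd$kind == "discrete") {
        u <- runif(n)
        cum <- apply(nd$cpt, 2, cumsum)
        code <- as.integer(rowSums(u > t(cum)[cfg, , drop = FALSE])) + 1L
        values[[nm]] <- factor(nd$levels[code], levels = nd$levels)
        bands[[nm]] <- code
      } else if (nd$kind == "lnorm") {
        mu <- nd$base + (nd$cfg_shift %||% 0)[cfg]
        v <- rlnorm(n, mu, nd$sd)
        values[[nm]] <- v
        bands[[nm]] <- band_code(v, nd$cuts)
      } else if (nd$kind == "tnorm") {
        mu <- nd$base + (nd$cfg_shift %||% 0)[cfg]
        v <- rtnorm_vec(n, mu, nd$sd, nd$bounds[1], nd$bounds[2])
        values[[nm]] <- v
        bands[[nm]] <- band_code(v, nd$cuts)
      } else if (nd$kind == "count3") {
        lmu <- nd$base + (nd$cfg_shift %||% 0)[cfg]
        cnt <- rnbinom(n, size = nd$size, mu = exp(lmu))
        code <- as.integer(pmin(cnt, 2)) + 1L
        values[[nm]] <- factor(nd$levels[code], levels = nd$levels)
        bands[[nm]] <- code
      } else stop2("unknown node kind '%s'", nd$kind)
    }
    out <- as.data.frame(values)
    if (spec$preset %in% c("core9", "extended15")) {
      for (ex in setdiff(names(extra_column_samplers()), names(out))) {
        out[[ex]] <- extra_column_samplers()[[ex]](n)
      }
    }
    out$patient_id <- seq_len(n)
    keep <- intersect(cohort_column_order(), names(out))
    out <- out[c(keep, setdiff(names(out), keep))]
    bm <- do.call(cbind, bands)
    attr(out, "bands") <- bm
    attr(out, "preset") <- spec$preset
    out
  })
}

#' Inject missing cells into a cohort
#'
#' Masks cells according to the spec's missingness block (or an explicit
#' list): MCAR masks uniformly at the configured rate; MAR masks with
#' per-stratum odds multipliers of a driver column, with the base rate
#' solved so the overall expected fraction equals the configured rate.
#' Outcome columns are never masked; a MAR driver may not itself be a
#' masking target.
#'
#' @param cohort A cohort data frame.
#' @param spec A `ground_truth_spec` (its `missingness` block is used) or a
#'   list of `list(column, rate, mechanism, driver, odds)` entries.
#' @param seed Integer seed.
#' @return The cohort with `NA` cells; attribute `"missingness"` logs the
#'   realized per-column fractions.
#' @export
inject_missingness <- function(cohort, spec, seed) {
  plan <- if (inherits(spec, "ground_truth_spec")) spec$missingness else spec
  if (!length(plan)) return(cohort)
  targets <- vapply(plan, `[[`, "", "column")
  for (ms in plan) {
    if (!is.null(ms$driver) && ms$driver %in% targets) {
      stop2("MAR driver '%s' is itself targeted for masking", ms$driver,
            class = "exacnet_config_error")
    }
  }
  if (any(targets %in% c("future_exac", "prior_exac"))) {
    stop2("outcome/exacerbation columns may not be masked", class = "exacnet_config_error")
  }
  withr::with_seed(seed, {
    realized <- numeric(0)
    for (ms in plan) {
      col <- ms$column
      if (!col %in% names(cohort)) next
      assert_scalar_prob(ms$rate, "rate", open_right = TRUE)
      n <- nrow(cohort)
      if (ms$rate == 0) { realized[col] <- 0; next }
      if (is.null(ms$mechanism) || ms$mechanism == "MCAR") {
        mask <- runif(n) < ms$rate
      } else if (ms$mechanism == "MAR") {
        drv <- cohort[[ms$driver]]
        if (anyNA(drv)) stop2("MAR driver '%s' must be fully observed", ms$driver,
                              class = "exacnet_config_error")
        odds <- ms$odds
        ol <- log(unname(odds[as.character(drv)]))
        pl <- vapply(levels(factor(drv)), function(l) mean(drv == l), 1.0)
        base <- uniroot(function(b)
          sum(pl * stats::plogis(b + log(unname(odds[names(pl)])))) - ms$rate,
          c(-20, 20), tol = 1e-10)$root
        mask <- runif(n) < stats::plogis(base + ol)
      } else stop2("unknown missingness mechanism '%s'", ms$mechanism)
      cohort[[col]][mask] <- NA
      realized[col] <- mean(mask)
    }
    attr(cohort, "missingness") <- realized
    cohort
  })
}

#' Assign country labels and re-draw the outcome with country effects
#'
#' Labels each patient with one of `k_countries` countries (uniformly at
#' random) and re-generates the future-exacerbation outcome with a
#' per-country multiplicative shift of the generating rate,
#' log-multipliers drawn N(0, `effect_sd`). With `effect_sd = 0` the outcome
#' distribution is identical across countries in expectation.
#'
#' @param cohort A cohort sampled from `spec`.
#' @param spec The generating `ground_truth_spec`.
#' @param k_countries Number of countries (>= 2).
#' @param effect_sd Standard deviation of the log rate multipliers.
#' @param seed Integer seed.
#' @return The cohort with `country` and re-drawn `future_exac`; attribute
#'   `"country_multipliers"` records the multipliers.
#' @export
assign_country <- function(cohort, spec, k_countries, effect_sd, seed) {
  stopifnot(k_countries >= 2)
  spec <- validate_ground_truth(spec)
  nd <- spec$nodes$future_exac
  withr::with_seed(seed, {
    k <- as.integer(k_countries)
    lmult <- rnorm(k, 0, effect_sd)
    labels <- sprintf("C%02d", seq_len(k))
    ctry <- sample.int(k, nrow(cohort), replace = TRUE)
    # rebuild the parent configuration from cohort values, swapping the old
    # country shift for the new one
    pa <- setdiff(nd$parents, "country")
    nlev <- vapply(spec$nodes, function(x) length(x$levels), 1L)
    codes <- vapply(pa, function(p) {
      pn <- spec$nodes[[p]]
      if (pn$kind %in% c("lnorm", "tnorm")) band_code(cohort[[p]], pn$cuts)
      else as.integer(factor(cohort[[p]], levels = pn$levels))
    }, integer(nrow(cohort)))
    shifts_np <- nd$shifts[match(pa, nd$parents)]
    shift <- rep(0, nrow(cohort))
    for (j in seq_along(pa)) shift <- shift + shifts_np[[j]][codes[, j]]
    lmu <- nd$base + shift + lmult[ctry]
    cnt <- rnbinom(nrow(cohort), size = nd$size, mu = exp(lmu))
    cohort$future_exac <- factor(nd$levels[pmin(cnt, 2L) + 1L], levels = nd$levels)
    cohort$country <- factor(labels[ctry], levels = labels)
    attr(cohort, "country_multipliers") <- setNames(exp(lmult), labels)
    cohort
  })
}

#' Write / read a cohort as CSV
#'
#' Fixed documented header (the cohort's column order); missing cells are
#' written as empty fields. Reading restores factor levels for the
#' categorical columns.
#'
#' @param cohort A cohort data frame.
#' @param path File path.
#' @return `path` (write) or the cohort data frame (read).
#' @export
write_cohort_csv <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  fct <- list(sex = c("Male", "Female"), crs = c("None", "CRSwoNP", "CRSwNP"),
              er_visits = c("0", "1", "2+"),
              invasive_ventilation = c("No", "Yes"), lama = c("No", "Yes"),
              macrolide = c("No", "Yes"), anxiety = c("No", "Yes"),
              eczema = c("No", "Yes"), prior_exac = c("0", "1", "2+"),
              future_exac = c("0", "1", "2+"))
  for (cn in names(fct)) {
    if (cn %in% names(out)) out[[cn]] <- factor(out[[cn]], levels = fct[[cn]])
  }
  if ("country" %in% names(out)) out$country <- factor(out$country)
  out
}
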