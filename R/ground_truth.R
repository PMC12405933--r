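# Ground-truth pathway networks for synthetic severe-asthma cohorts.
#
# Every node carries (i) a band-level conditional probability table over its
# parents' bands and (ii) enough distributional detail to draw the actual
# value (continuous measurements, latent exacerbation counts). Because the
# location shifts of continuous nodes depend on parent bands only, the joint
# distribution of the banded variables is itself an exact discrete Bayesian
# network, recoverable in closed form via true_discrete_net().

# ---- distributional helpers ------------------------------------------------

band_probs_lnorm <- function(meanlog, sdlog, cuts) {
  p <- diff(c(0, plnorm(cuts, meanlog, sdlog), 1))
  p / sum(p)
}

band_probs_tnorm <- function(mean, sd, cuts, lo, hi) {
  plo <- pnorm(lo, mean, sd); phi <- pnorm(hi, mean, sd)
  cdf <- (pnorm(pmin(pmax(cuts, lo), hi), mean, sd) - plo) / (phi - plo)
  p <- diff(c(0, cdf, 1))
  p / sum(p)
}

nb_level_probs <- function(log_mu, size) {
  mu <- exp(log_mu)
  p0 <- dnbinom(0, size = size, mu = mu)
  p1 <- dnbinom(1, size = size, mu = mu)
  c(p0, p1, pmax(1 - p0 - p1, 0))
}

# mixed-radix configuration count/index over parent level counts
ncfg_of <- function(nlevs) if (!length(nlevs)) 1L else prod(nlevs)

cfg_index_codes <- function(codes_mat, nlevs) {
  # codes_mat: n x p integer (1-based), first column fastest
  if (!NCOL(codes_mat) || !length(nlevs)) return(rep(1L, NROW(codes_mat)))
  idx <- rep(1L, nrow(codes_mat))
  stride <- 1L
  for (j in seq_along(nlevs)) {
    idx <- idx + (codes_mat[, j] - 1L) * stride
    stride <- stride * nlevs[j]
  }
  idx
}

# total additive shift per parent configuration; shifts is a list (one numeric
# vector per parent, indexed by parent level)
shift_per_cfg <- function(parent_nlevs, shifts) {
  ncfg <- ncfg_of(parent_nlevs)
  if (ncfg == 1L) return(0)
  grid <- expand.grid(lapply(parent_nlevs, seq_len))
  tot <- rep(0, ncfg)
  for (j in seq_along(shifts)) tot <- tot + shifts[[j]][grid[[j]]]
  tot
}

# ---- node constructors -----------------------------------------------------

gt_node_discrete <- function(name, levels, parents = character(0), cpt) {
  cpt <- as.matrix(cpt)
  stopifnot(nrow(cpt) == length(levels))
  list(name = name, type = if (length(levels) == 2L) "nominal" else "nominal",
       kind = "discrete", levels = levels, parents = parents, cpt = cpt)
}

gt_node_continuous <- function(name, parents, dist, base, shifts, sd, cuts,
                               bounds = c(0, Inf), band_labels = c("low", "mid", "high")) {
  parent_nlevs <- integer(0) # filled by finalize
  list(name = name, type = "continuous", kind = dist, levels = band_labels,
       parents = parents, base = base, shifts = shifts, sd = sd, cuts = cuts,
       bounds = bounds, cpt = NULL)
}

gt_node_count3 <- function(name, parents, log_mu_base, shifts, size,
                           levels = c("0", "1", "2+")) {
  list(name = name, type = "ordinal", kind = "count3", levels = levels,
       parents = parents, base = log_mu_base, shifts = shifts, size = size,
       cpt = NULL)
}

# compute the band-level CPT of a non-discrete node from its parents' levels
finalize_node_cpt <- function(node, nlev_by_node) {
  if (node$kind == "discrete") return(node)
  pn <- unname(nlev_by_node[node$parents])
  tot_shift <- shift_per_cfg(pn, node$shifts)
  ncfg <- ncfg_of(pn)
  cpt <- matrix(0, nrow = length(node$levels), ncol = ncfg)
  for (k in seq_len(ncfg)) {
    cpt[, k] <- switch(node$kind,
      lnorm  = band_probs_lnorm(node$base + tot_shift[k], node$sd, node$cuts),
      tnorm  = band_probs_tnorm(node$base + tot_shift[k], node$sd, node$cuts,
                                node$bounds[1], node$bounds[2]),
      count3 = nb_level_probs(node$base + tot_shift[k], node$size),
      stop2("unknown node kind '%s'", node$kind))
  }
  node$cfg_shift <- tot_shift
  node$cpt <- cpt
  node
}

# ---- spec assembly and validation ------------------------------------------

new_ground_truth_spec <- function(nodes, missingness = list(), country = NULL,
                                  preset = "custom") {
  names(nodes) <- vapply(nodes, `[[`, "", "name")
  spec <- structure(list(nodes = nodes, missingness = missingness,
                         country = country, preset = preset),
                    class = "ground_truth_spec")
  validate_ground_truth(spec)
}

#' Validate a ground-truth specification
#'
#' Checks the structural invariants: the arc set is acyclic, every
#' conditional probability column sums to 1 within 1e-12, all missingness
#' rates lie in `[0, 1)`, and parents precede children consistently.
#'
#' @param spec A `ground_truth_spec`.
#' @return The spec, invisibly usable, after validation (errors otherwise).
#' @export
validate_ground_truth <- function(spec) {
  stopifnot(inherits(spec, "ground_truth_spec"))
  nodes <- spec$nodes
  nms <- names(nodes)
  # directed acyclicity over the parent lists (a mutual parent pair is a
  # 2-cycle here, not an undirected edge)
  dmat <- matrix(0L, length(nms), length(nms), dimnames = list(nms, nms))
  for (nd in nodes) {
    bad <- setdiff(nd$parents, nms)
    if (length(bad)) stop2("node '%s' has unknown parent(s): %s", nd$name,
                           paste(bad, collapse = ", "))
    dmat[nd$parents, nd$name] <- 1L
  }
  indeg <- colSums(dmat)
  active <- rep(TRUE, length(nms))
  repeat {
    roots <- which(active & indeg == 0L)
    if (!length(roots)) break
    for (r in roots) { indeg <- indeg - dmat[r, ]; active[r] <- FALSE }
  }
  if (any(active)) {
    stop2("arc set is cyclic (involving: %s)", paste(nms[active], collapse = ", "),
          class = "exacnet_cycle_error")
  }
  arcs <- do.call(rbind, lapply(nodes, function(nd)
    if (length(nd$parents)) cbind(nd$parents, nd$name) else NULL))
  g <- bn_graph(nms, arcs = arcs)
  nlev <- vapply(nodes, function(nd) length(nd$levels), 1L)
  for (nd in nodes) {
    if (is.null(nd$cpt)) stop2("node '%s' has no conditional table; finalize the spec", nd$name)
    ncfg <- ncfg_of(unname(nlev[nd$parents]))
    if (ncol(nd$cpt) != ncfg || nrow(nd$cpt) != length(nd$levels)) {
      stop2("CPT of node '%s' has wrong dimensions", nd$name, class = "exacnet_validation_error")
    }
    if (any(abs(colSums(nd$cpt) - 1) > 1e-12) || any(nd$cpt < 0)) {
      stop2("CPT of node '%s' has a column not summing to 1", nd$name,
            class = "exacnet_validation_error")
    }
  }
  for (ms in spec$missingness) {
    if (!is.numeric(ms$rate) || ms$rate < 0 || ms$rate >= 1) {
      stop2("missingness rate for '%s' must be in [0, 1)", ms$column,
            class = "exacnet_validation_error")
    }
  }
  attr(spec, "graph") <- g
  spec
}

#' @export
print.ground_truth_spec <- function(x, ...) {
  cat(sprintf("Ground-truth pathway spec '%s': %d nodes, %d arcs, %d columns with missingness\n",
              x$preset, length(x$nodes),
              nrow(arcs(attr(validate_ground_truth(x), "graph"))),
              length(x$missingness)))
  invisible(x)
}

# exact joint over the banded variables (topological node order; first node
# fastest in the returned configuration grid)
enumerate_spec_joint <- function(spec, upto = names(spec$nodes)) {
  nodes <- spec$nodes[upto]
  nlev <- vapply(nodes, function(nd) length(nd$levels), 1L)
  grid <- as.matrix(expand.grid(lapply(nlev, seq_len)))
  prob <- rep(1, nrow(grid))
  for (nd in nodes) {
    cfg <- cfg_index_codes(grid[, nd$parents, drop = FALSE], unname(nlev[nd$parents]))
    prob <- prob * nd$cpt[cbind(grid[, nd$name], cfg)]
  }
  list(grid = grid, prob = prob, nlev = nlev)
}

# marginal probability vector over the configurations of `cols` (in that
# order, first column fastest)
parent_config_probs <- function(spec, cols) {
  jt <- enumerate_spec_joint(spec)
  if (!length(cols)) return(1)
  cfg <- cfg_index_codes(jt$grid[, cols, drop = FALSE], unname(jt$nlev[cols]))
  out <- numeric(ncfg_of(unname(jt$nlev[cols])))
  agg <- tapply(jt$prob, cfg, sum)
  out[as.integer(names(agg))] <- agg
  out
}

# ---- presets ---------------------------------------------------------------

# clinical band cuts shared by the generator and the default preprocessing
default_clinical_cuts <- function() {
  list(age = c(40, 60), bec = c(150, 300), feno = c(25, 50), fev1pp = c(60, 80))
}

#' Build a ground-truth pathway network
#'
#' Returns the generating model for synthetic severe-asthma cohorts. The
#' `"core9"` preset contains the 9 pathway variables (age, sex, chronic
#' rhinosinusitis, macrolide use, blood eosinophil count, Feno, % predicted
#' FEV1, prior and future severe exacerbations) plus a country node — a
#' 10-node DAG in which CRS drives the biomarkers and lung function, these
#' drive both exacerbation variables, prior exacerbations drive future ones,
#' and age/sex/macrolide act from the upper stream. `"extended15"` adds six
#' downstream variables (IgE, FEV1 reversibility, ER visits, invasive
#' ventilation, LAMA use, anxiety). Marginals are calibrated so that, e.g.,
#' P(female) = 0.612, P(CRS with polyps) = 0.311, P(macrolide) = 0.119 and
#' the mean prior/future 12-month exacerbation counts are 0.5 and 0.2;
#' intercepts of conditional nodes are solved at build time from the exact
#' band-level joint.
#'
#' @param preset `"core9"` or `"extended15"`, or `"custom"` with `nodes`.
#' @param k_countries Number of countries (default 10).
#' @param country_effect_sd Standard deviation of per-country log outcome-rate
#'   multipliers (default 0.3; multipliers are deterministic normal quantiles,
#'   so the spec itself is seed-free).
#' @param macrolide_to_prior Also include the optional Macrolide -> PriorExac
#'   arc (default `FALSE`).
#' @param nodes For `preset = "custom"`: a list of finalized node entries.
#' @param missingness Optional list of per-column missingness settings, each
#'   `list(column, rate, mechanism = "MCAR"|"MAR", driver, odds)`; defaults
#'   emulate registry biomarker missingness.
#' @return A validated `ground_truth_spec`.
#' @examples
#' spec <- make_ground_truth_network("core9")
#' spec$nodes$sex$cpt # P(male), P(female)
#' @export
make_ground_truth_network <- function(preset = c("core9", "extended15", "custom"),
                                      k_countries = 10L, country_effect_sd = 0.3,
                                      macrolide_to_prior = FALSE, nodes = NULL,
                                      missingness = NULL) {
  preset <- match.arg(preset)
  if (preset == "custom") {
    if (is.null(nodes)) stop2("custom spec requires `nodes`")
    return(new_ground_truth_spec(nodes, missingness %||% list(), preset = "custom"))
  }
  cuts <- default_clinical_cuts()
  b3 <- c("low", "mid", "high")

  # roots ---------------------------------------------------------------
  age <- finalize_node_cpt(gt_node_continuous(
    "age", character(0), "tnorm", base = 55.2, shifts = list(), sd = 15.1,
    cuts = cuts$age, bounds = c(18, 95)), integer(0))
  sex <- gt_node_discrete("sex", c("Male", "Female"), cpt = matrix(c(0.388, 0.612)))
  k <- as.integer(k_countries)
  country_mult <- exp(country_effect_sd * qnorm(seq_len(k) / (k + 1)))
  country <- gt_node_discrete("country", sprintf("C%02d", seq_len(k)),
                              cpt = matrix(rep(1 / k, k)))
  country$log_mult <- log(country_mult)

  nlev <- c(age = 3L, sex = 2L, country = k)

  # CRS <- age + sex: multinomial logit, intercepts solved so the marginal
  # hits (None .489, CRSwoNP .200, CRSwNP .311); CRS is commoner in women
  # and at older ages, nasal polyps most of all
  p_age <- band_probs_tnorm(55.2, 15.1, cuts$age, 18, 95)
  p_sex <- c(0.388, 0.612)
  crs_beta <- list(wonp = c(age = 0.60, fem = 0.50), wnp = c(age = 0.90, fem = 0.85))
  crs_cpt_of <- function(a) {
    cpt <- matrix(0, 3, 6) # cfg order: age fastest, then sex
    for (s in 1:2) for (ag in 1:3) {
      u <- c(0,
             a[1] + crs_beta$wonp["age"] * (ag - 1) + crs_beta$wonp["fem"] * (s - 1),
             a[2] + crs_beta$wnp["age"] * (ag - 1) + crs_beta$wnp["fem"] * (s - 1))
      cpt[, ag + 3 * (s - 1)] <- exp(u) / sum(exp(u))
    }
    cpt
  }
  crs_target <- c(0.489, 0.200, 0.311)
  crs_marg <- function(a) {
    cpt <- crs_cpt_of(a)
    w <- as.vector(outer(p_age, p_sex)) # age fastest
    as.vector(cpt %*% w)
  }
  sol <- optim(c(-1, -1), function(a) sum((crs_marg(a) - crs_target)^2),
               method = "BFGS", control = list(reltol = 1e-14))
  crs <- gt_node_discrete("crs", c("None", "CRSwoNP", "CRSwNP"),
                          parents = c("age", "sex"), cpt = crs_cpt_of(sol$par))

  # macrolide <- age: logistic in age band, marginal 0.119
  mac_beta <- 1.20
  mac_base <- uniroot(function(b)
    sum(p_age * stats::plogis(b + mac_beta * (0:2))) - 0.119, c(-10, 5), tol = 1e-12)$root
  mac_cpt <- vapply(0:2, function(ag) {
    p <- stats::plogis(mac_base + mac_beta * ag); c(1 - p, p)
  }, numeric(2))
  macrolide <- gt_node_discrete("macrolide", c("No", "Yes"), parents = "age",
                                cpt = mac_cpt)

  # biomarkers and lung function <- CRS (bands shift location) -----------
  p_crs <- crs_target
  bec_sd <- 0.65
  bec_shift <- list(c(0, 0.45, 0.85))                      # None, woNP, wNP
  bec_base <- log(426.4) - bec_sd^2 / 2 - log(sum(p_crs * exp(bec_shift[[1]])))
  bec <- gt_node_continuous("bec", "crs", "lnorm", bec_base, bec_shift,
                            bec_sd, cuts$bec)

  fev_shift <- list(c(0, -8, -15))
  fev_base <- 73.6 - sum(p_crs * fev_shift[[1]])
  fev1pp <- gt_node_continuous("fev1pp", "crs", "tnorm", fev_base, fev_shift,
                               17, cuts$fev1pp, bounds = c(10, 180))

  spec0 <- list(age = age, sex = sex, country = country, crs = crs,
                macrolide = macrolide)
  nlev_all <- c(nlev, crs = 3L, macrolide = 2L, bec = 3L, fev1pp = 3L,
                feno = 3L, prior_exac = 3L, future_exac = 3L)
  fin <- function(nd) finalize_node_cpt(nd, nlev_all)
  spec0$bec <- fin(bec)
  spec0$fev1pp <- fin(fev1pp)

  # feno <- crs + bec + fev1pp; calibrated to mean 41.8 ppb
  feno_sd <- 0.60
  feno_shifts <- list(c(0, 0.30, 0.55),      # crs
                      c(0, 0.30, 0.60),      # bec band
                      c(0.55, 0.28, 0))      # fev1pp band (worse lung, higher)
  tmp <- new_ground_truth_spec(lapply(spec0, identity), preset = "partial")
  p_cfb <- parent_config_probs(tmp, c("crs", "bec", "fev1pp"))
  sh <- shift_per_cfg(c(3L, 3L, 3L), feno_shifts)
  feno_base <- log(41.8) - feno_sd^2 / 2 - log(sum(p_cfb * exp(sh)))
  spec0$feno <- fin(gt_node_continuous("feno", c("crs", "bec", "fev1pp"), "lnorm",
                                       feno_base, feno_shifts, feno_sd, cuts$feno))

  # prior exacerbations <- bec + feno + fev1pp (latent negative binomial,
  # mean 0.5/12mo, thresholded at 0 / 1 / >= 2)
  prior_shifts <- list(c(0, 0.80, 1.60),     # bec
                       c(0, 0.70, 1.40),     # feno
                       c(1.40, 0.70, 0))     # fev1pp
  if (macrolide_to_prior) prior_shifts <- c(prior_shifts, list(c(0, 0.60)))
  prior_parents <- c("bec", "feno", "fev1pp", if (macrolide_to_prior) "macrolide")
  tmp <- new_ground_truth_spec(lapply(spec0, identity), preset = "partial")
  p_pp <- parent_config_probs(tmp, prior_parents)
  sh <- shift_per_cfg(unname(nlev_all[prior_parents]), prior_shifts)
  prior_base <- log(0.5) - log(sum(p_pp * exp(sh)))
  spec0$prior_exac <- fin(gt_node_count3("prior_exac", prior_parents, prior_base,
                                         prior_shifts, size = 0.30))

  # future exacerbations <- prior + bec + feno + fev1pp + macrolide + country
  fut_parents <- c("prior_exac", "bec", "feno", "fev1pp", "macrolide", "country")
  fut_shifts <- list(c(0, 1.20, 2.10),       # prior exacerbations
                     c(0, 0.80, 1.60),       # bec
                     c(0, 0.70, 1.40),       # feno
                     c(1.30, 0.65, 0),       # fev1pp
                     c(0, 1.10),             # macrolide
                     country$log_mult)       # country rate multiplier
  tmp <- new_ground_truth_spec(lapply(spec0, identity), preset = "partial")
  p_fp <- parent_config_probs(tmp, fut_parents)
  sh <- shift_per_cfg(unname(nlev_all[fut_parents]), fut_shifts)
  fut_base <- log(0.2) - log(sum(p_fp * exp(sh)))
  spec0$future_exac <- fin(gt_node_count3("future_exac", fut_parents, fut_base,
                                          fut_shifts, size = 0.35))

  if (preset == "extended15") {
    tmp <- new_ground_truth_spec(lapply(spec0, identity), preset = "partial")
    p_bec <- parent_config_probs(tmp, "bec")
    p_fev <- parent_config_probs(tmp, "fev1pp")
    p_pri <- parent_config_probs(tmp, "prior_exac")
    ige_sd <- 1.32
    ige_shift <- list(c(0, 0.30, 0.60))
    ige_base <- log(406.7) - ige_sd^2 / 2 - log(sum(p_bec * exp(ige_shift[[1]])))
    spec0$ige <- fin(gt_node_continuous("ige", "bec", "lnorm", ige_base, ige_shift,
                                        ige_sd, cuts = c(100, 400)))
    rev_shift <- list(c(3.5, 0, -2))
    rev_base <- 5.5 - sum(p_fev * rev_shift[[1]])
    spec0$fev1_reversibility <- fin(gt_node_continuous(
      "fev1_reversibility", "fev1pp", "tnorm", rev_base, rev_shift, 9.1,
      cuts = c(4, 12), bounds = c(0, 60)))
    er_shift <- list(c(0, 0.9, 1.8))
    er_base <- log(0.2) - log(sum(p_pri * exp(er_shift[[1]])))
    spec0$er_visits <- fin(gt_node_count3("er_visits", "prior_exac", er_base,
                                          er_shift, size = 0.30))
    solve_bern <- function(target, odds, pw) {
      b <- uniroot(function(b0) sum(pw * stats::plogis(b0 + log(odds))) - target,
                   c(-12, 6), tol = 1e-12)$root
      vapply(seq_along(odds), function(l) {
        p <- stats::plogis(b + log(odds[l])); c(1 - p, p)
      }, numeric(2))
    }
    spec0$invasive_ventilation <- gt_node_discrete(
      "invasive_ventilation", c("No", "Yes"), parents = "prior_exac",
      cpt = solve_bern(0.01, c(1, 2, 4), p_pri))
    spec0$anxiety <- gt_node_discrete(
      "anxiety", c("No", "Yes"), parents = "prior_exac",
      cpt = solve_bern(0.074, c(1, 1.5, 2), p_pri))
    spec0$lama <- gt_node_discrete(
      "lama", c("No", "Yes"), parents = "fev1pp",
      cpt = solve_bern(0.083, c(2.5, 1.5, 1), p_fev))
  }

  miss_default <- list(
    list(column = "bec", rate = 0.08, mechanism = "MCAR"),
    list(column = "feno", rate = 0.12, mechanism = "MAR", driver = "crs",
         odds = c(None = 1, CRSwoNP = 0.7, CRSwNP = 0.5)),
    list(column = "ige", rate = 0.15, mechanism = "MCAR"),
    list(column = "fev1_reversibility", rate = 0.10, mechanism = "MCAR")
  )
  new_ground_truth_spec(spec0, missingness = missingness %||% miss_default,
                        country = list(k = k, multipliers = country_mult),
                        preset = preset)
}

# pathway columns used for structure learning (country is a grouping
# variable, not a predictor)
pathway_nodes <- function(spec) setdiff(names(spec$nodes), "country")

#' True band-level discrete network of a ground-truth spec
#'
#' Derives, in closed form, the discrete Bayesian network induced by the
#' generator on the banded variables (clinical bands for continuous nodes,
#' native levels otherwise). This is exact because continuous nodes shift
#' location per parent band configuration only.
#'
#' @param spec A `ground_truth_spec`.
#' @param include_country Keep the country node (default `FALSE`: the
#'   pathway network over predictors and outcome, with country marginalized
#'   out of the future-exacerbation table).
#' @return A fitted discrete network (class `exacnet_dbn`).
#' @export
true_discrete_net <- function(spec, include_country = FALSE) {
  spec <- validate_ground_truth(spec)
  nodes <- spec$nodes
  if (!include_country && "country" %in% names(nodes)) {
    # marginalize country out of its children's tables
    pk <- as.vector(nodes$country$cpt)
    for (nm in names(nodes)) {
      nd <- nodes[[nm]]
      if (!"country" %in% nd$parents) next
      nlev <- vapply(nodes, function(x) length(x$levels), 1L)
      pn <- unname(nlev[nd$parents])
      grid <- as.matrix(expand.grid(lapply(pn, seq_len)))
      keep <- setdiff(nd$parents, "country")
      pk_idx <- grid[, which(nd$parents == "country")]
      new_cfg <- cfg_index_codes(grid[, which(nd$parents != "country"), drop = FALSE],
                                 unname(nlev[keep]))
      new_cpt <- matrix(0, nrow(nd$cpt), ncfg_of(unname(nlev[keep])))
      for (r in seq_len(nrow(grid))) {
        new_cpt[, new_cfg[r]] <- new_cpt[, new_cfg[r]] + pk[pk_idx[r]] * nd$cpt[, r]
      }
      nd$parents <- keep
      nd$cpt <- new_cpt
      nodes[[nm]] <- nd
    }
    nodes$country <- NULL
  }
  nlev <- vapply(nodes, function(x) length(x$levels), 1L)
  arcs <- do.call(rbind, lapply(nodes, function(nd)
    if (length(nd$parents)) cbind(nd$parents, nd$name) else NULL))
  g <- bn_graph(names(nodes), arcs = arcs)
  levels <- lapply(nodes, `[[`, "levels")
  cpts <- lapply(nodes, function(nd) {
    pn <- unname(nlev[nd$parents])
    a <- array(nd$cpt, dim = c(length(nd$levels), pn),
               dimnames = c(list(nd$levels), unname(levels[nd$parents])))
    names(dimnames(a)) <- c(nd$name, nd$parents)
    a
  })
  new_dbn(g, levels, cpts, n = NA_integer_, alpha = 0)
}

#' True CPDAG of the pathway network
#'
#' Equivalence-class representative of the generator's DAG over the pathway
#' variables (country excluded), the reference for structure-recovery
#' evaluation.
#'
#' @param spec A `ground_truth_spec`.
#' @return A `bn_graph` CPDAG.
#' @export
true_cpdag <- function(spec) {
  spec <- validate_ground_truth(spec)
  keep <- pathway_nodes(spec)
  arcs <- do.call(rbind, lapply(spec$nodes[keep], function(nd) {
    pp <- intersect(nd$parents, keep)
    if (length(pp)) cbind(pp, nd$name) else NULL
  }))
  cpdag_of(bn_graph(keep, arcs = arcs))
}

# ---- JSON serialization ----------------------------------------------------

#' Write / read a ground-truth spec as JSON
#'
#' @param spec A `ground_truth_spec`.
#' @param path File path.
#' @return `path` (write) or a validated `ground_truth_spec` (read).
#' @export
write_ground_truth_json <- function(spec, path) {
  spec <- validate_ground_truth(spec)
  ser <- list(preset = spec$preset,
              country = spec$country,
              missingness = spec$missingness,
              nodes = lapply(spec$nodes, function(nd) {
                nd$cpt <- as.vector(nd$cpt)
                nd
              }))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_ground_truth_json
#' @export
read_ground_truth_json <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  nodes <- lapply(ser$nodes, function(nd) {
    nd$parents <- as.character(unlist(nd$parents %||% character(0)))
    nd$levels <- as.character(unlist(nd$levels))
    nd
  })
  nlev <- vapply(nodes, function(nd) length(nd$levels), 1L)
  nodes <- lapply(nodes, function(nd) {
    ncfg <- ncfg_of(unname(nlev[nd$parents]))
    nd$cpt <- matrix(as.numeric(unlist(nd$cpt)), nrow = length(nd$levels), ncol = ncfg)
    if (!is.null(nd$shifts)) nd$shifts <- lapply(nd$shifts, as.numeric)
    nd
  })
  miss <- lapply(ser$missingness %||% list(), function(ms) {
    ms$rate <- as.numeric(ms$rate)
    if (!is.null(ms$odds)) ms$odds <- unlist(ms$odds)
    ms
  })
  new_ground_truth_spec(nodes, miss, ser$country, ser$preset %||% "custom")
}
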