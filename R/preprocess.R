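# Registry-style preprocessing: zero/outlier recoding, discretization by
# clinical thresholds or mutual-information preserving (Hartemink) merging.

#' Recode zeros and out-of-bounds values as missing
#'
#' Biomarker zeros (by default in BEC, Feno and IgE, where a recorded 0 is a
#' measurement artefact) and values outside configured plausibility bounds
#' are set to missing for subsequent imputation.
#'
#' @param cohort A cohort data frame.
#' @param rules List with `zero_columns` (character) and `bounds` (named
#'   list of `c(lower, upper)`; values outside the closed interval are
#'   recoded). Defaults: zeros in bec/feno/ige; bounds bec (0, 20000],
#'   feno (0, 500], ige (0, 20000], fev1pp (10, 180), age [18, 110].
#' @return The recoded cohort; attribute `"recode_log"` is a data frame
#'   (column, n_zero, n_outlier).
#' @export
recode_zeros_and_outliers <- function(cohort, rules = NULL) {
  rules <- rules %||% list(
    zero_columns = c("bec", "feno", "ige"),
    bounds = list(bec = c(0, 20000), feno = c(0, 500), ige = c(0, 20000),
                  fev1pp = c(10, 180), age = c(18, 110)))
  unknown <- setdiff(c(rules$zero_columns, names(rules$bounds)), names(cohort))
  if (length(unknown)) {
    stop2("recode rule references unknown column(s): %s",
          paste(unknown, collapse = ", "), class = "exacnet_config_error")
  }
  log <- list()
  for (cn in union(rules$zero_columns, names(rules$bounds))) {
    v <- cohort[[cn]]
    if (!is.numeric(v)) stop2("recode rules apply to numeric columns; '%s' is not", cn)
    nz <- 0L; no <- 0L
    if (cn %in% rules$zero_columns) {
      zero <- !is.na(v) & v == 0
      nz <- sum(zero)
      v[zero] <- NA
    }
    b <- rules$bounds[[cn]]
    if (!is.null(b)) {
      out <- !is.na(v) & (v < b[1] | v > b[2])
      no <- sum(out)
      v[out] <- NA
    }
    if (nz + no > 0L) log[[length(log) + 1L]] <-
        data.frame(column = cn, n_zero = nz, n_outlier = no)
    cohort[[cn]] <- v
  }
  attr(cohort, "recode_log") <- if (length(log)) do.call(rbind, log) else
    data.frame(column = character(0), n_zero = integer(0), n_outlier = integer(0))
  cohort
}

#' Discretize a numeric column at fixed clinical thresholds
#'
#' Half-open binning with the boundary assigned upward: level i holds values
#' in `[cut_{i-1}, cut_i)`, the lowest bin open below, so a value equal to a
#' cut point falls in the upper bin.
#'
#' @param column Numeric vector.
#' @param cuts Strictly increasing cut points.
#' @param labels Level labels (length `length(cuts) + 1`); default
#'   low/mid/high for two cuts, `b1..bk` otherwise.
#' @return Factor of the same length (NA preserved).
#' @examples
#' fixed_clinical_cuts(c(100, 150, 500), c(150, 300)) # low, mid, high
#' @export
fixed_clinical_cuts <- function(column, cuts, labels = NULL) {
  if (length(cuts) < 1L || is.unsorted(cuts, strictly = TRUE)) {
    stop2("cuts must be strictly increasing")
  }
  if (!is.numeric(column)) stop2("fixed_clinical_cuts() requires a numeric column")
  labels <- labels %||% default_band_labels(length(cuts) + 1L)
  idx <- findInterval(column, cuts, left.open = FALSE) + 1L
  factor(labels[idx], levels = labels)
}

default_band_labels <- function(k) {
  if (k == 2L) c("low", "high") else if (k == 3L) c("low", "mid", "high")
  else paste0("b", seq_len(k))
}

# ---- DiscretizationMap -----------------------------------------------------

new_discretization_map <- function(entries) {
  structure(list(columns = entries), class = "discretization_map")
}

#' @export
print.discretization_map <- function(x, ...) {
  cat(sprintf("Discretization map for %d column(s):\n", length(x$columns)))
  for (cn in names(x$columns)) {
    e <- x$columns[[cn]]
    cat(sprintf("  %-20s %-10s cuts: %s\n", cn, e$method,
                paste(signif(e$cuts, 6), collapse = ", ")))
  }
  invisible(x)
}

#' Apply a discretization map to new data
#'
#' Reapplies the stored cut points (identical convention as fitting) to a
#' cohort, e.g. to test folds or new patients.
#'
#' @param map A `discretization_map`.
#' @param cohort Data frame.
#' @return The cohort with mapped columns replaced by factors.
#' @export
apply_discretization <- function(map, cohort) {
  for (cn in names(map$columns)) {
    if (!cn %in% names(cohort)) next
    e <- map$columns[[cn]]
    if (!length(e$cuts)) {
      cohort[[cn]] <- factor(rep(e$labels[1], nrow(cohort)), levels = e$labels)
    } else {
      cohort[[cn]] <- fixed_clinical_cuts(cohort[[cn]], e$cuts, e$labels)
    }
  }
  cohort
}

#' Write / read a discretization map as JSON
#' @param map A `discretization_map`.
#' @param path File path.
#' @return `path` (write) or a `discretization_map` (read).
#' @export
write_discretization_json <- function(map, path) {
  jsonlite::write_json(map$columns, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_discretization_json
#' @export
read_discretization_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  entries <- lapply(raw, function(e)
    list(method = e$method, cuts = as.numeric(unlist(e$cuts)),
         labels = as.character(unlist(e$labels))))
  new_discretization_map(entries)
}

#' Discretize continuous columns at clinical thresholds
#'
#' Applies the default clinical bands (age 40/60 y, BEC 150/300 cells/uL,
#' Feno 25/50 ppb, FEV1 60/80 \% predicted, IgE 100/400 kU/L, reversibility
#' 4/12 \%), or user-supplied cuts, to every matching numeric column.
#'
#' @param cohort Data frame.
#' @param cuts Named list of cut vectors (defaults above).
#' @return List: `data` (discretized cohort) and `map`
#'   (a `discretization_map`).
#' @export
discretize_clinical <- function(cohort, cuts = NULL) {
  cuts <- cuts %||% c(default_clinical_cuts(),
                      list(ige = c(100, 400), fev1_reversibility = c(4, 12)))
  entries <- list()
  for (cn in intersect(names(cuts), names(cohort))) {
    if (!is.numeric(cohort[[cn]])) next
    labels <- default_band_labels(length(cuts[[cn]]) + 1L)
    cohort[[cn]] <- fixed_clinical_cuts(cohort[[cn]], cuts[[cn]], labels)
    entries[[cn]] <- list(method = "fixed_clinical", cuts = cuts[[cn]], labels = labels)
  }
  list(data = cohort, map = new_discretization_map(entries))
}

# ---- Hartemink discretization ----------------------------------------------

# pairwise mutual information between two integer-coded vectors
mi_pair <- function(x, nx, y, ny) {
  n <- length(x)
  cnt <- tabulate(x + nx * (y - 1L), nbins = nx * ny)
  p <- cnt / n
  px <- tabulate(x, nx) / n
  py <- tabulate(y, ny) / n
  e <- outer(px, py)
  pos <- p > 0
  sum(p[pos] * log(p[pos] / as.vector(e)[pos]))
}

#' Information-preserving (Hartemink) discretization
#'
#' Each continuous column is first quantile-binned into `initial_bins`
#' levels; adjacent bins are then merged greedily, at every step collapsing
#' the pair whose merge loses the least total pairwise mutual information
#' with all other variables, until `target_levels` remain. Non-targeted
#' discrete columns participate in the mutual-information totals.
#'
#' @param cohort Data frame (no missing values in targeted columns).
#' @param target_levels Final number of levels (>= 2).
#' @param initial_bins Starting quantile bins (>= `target_levels`).
#' @param columns Columns to discretize (default: all numeric except
#'   `patient_id`).
#' @return List: `data` and `map` as in [discretize_clinical()].
#' @export
discretize_hartemink <- function(cohort, target_levels = 3L, initial_bins = 10L,
                                 columns = NULL) {
  stopifnot(target_levels >= 2L, initial_bins >= target_levels)
  columns <- columns %||% setdiff(names(cohort)[vapply(cohort, is.numeric, TRUE)],
                                  "patient_id")
  bad <- columns[!vapply(cohort[columns], is.numeric, TRUE)]
  if (length(bad)) stop2("non-numeric column(s) targeted: %s", paste(bad, collapse = ", "))
  n <- nrow(cohort)
  # initial quantile binning for all targets
  codes <- list(); breaks <- list()
  for (cn in columns) {
    v <- cohort[[cn]]
    if (anyNA(v)) stop2("column '%s' has missing values; impute before discretizing", cn)
    if (length(unique(v)) == 1L) {
      warning(sprintf("column '%s' is constant; single level produced", cn))
      codes[[cn]] <- rep(1L, n); breaks[[cn]] <- numeric(0)
      next
    }
    qs <- unique(quantile(v, probs = seq_len(initial_bins - 1L) / initial_bins,
                          type = 7, names = FALSE))
    qs <- qs[qs > min(v)] # empty lowest bin would duplicate level 1
    if (!length(qs)) {
      codes[[cn]] <- rep(1L, n); breaks[[cn]] <- numeric(0)
      next
    }
    codes[[cn]] <- findInterval(v, qs, left.open = FALSE) + 1L
    breaks[[cn]] <- qs
  }
  # companion variables: other targets (current coding), discrete columns,
  # and quantile-coded numeric columns outside the target set
  disc_cols <- setdiff(names(cohort)[vapply(cohort, function(x)
    is.factor(x) || is.character(x), TRUE)], columns)
  disc_codes <- lapply(cohort[disc_cols], function(x) as.integer(factor(x)))
  num_extra <- setdiff(names(cohort)[vapply(cohort, is.numeric, TRUE)],
                       c(columns, "patient_id"))
  for (cn in num_extra) {
    v <- cohort[[cn]]
    if (anyNA(v)) next
    qs <- unique(quantile(v, probs = seq_len(initial_bins - 1L) / initial_bins,
                          type = 7, names = FALSE))
    if (length(qs)) disc_codes[[cn]] <- findInterval(v, qs) + 1L
  }
  for (cn in columns) {
    while (length(breaks[[cn]]) + 1L > target_levels) {
      x <- codes[[cn]]
      nx <- length(breaks[[cn]]) + 1L
      others <- c(codes[setdiff(columns, cn)], disc_codes)
      best_mi <- -Inf; best_k <- 1L
      for (k in seq_len(nx - 1L)) { # merge bins k and k+1
        xm <- x - (x > k)
        tot <- 0
        for (o in others) tot <- tot + mi_pair(xm, nx - 1L, o, max(o))
        if (tot > best_mi + 1e-12) { best_mi <- tot; best_k <- k }
      }
      codes[[cn]] <- x - (x > best_k)
      breaks[[cn]] <- breaks[[cn]][-best_k]
    }
  }
  entries <- list()
  for (cn in columns) {
    labels <- default_band_labels(length(breaks[[cn]]) + 1L)
    entries[[cn]] <- list(method = "hartemink", cuts = breaks[[cn]], labels = labels)
    cohort[[cn]] <- factor(labels[codes[[cn]]], levels = labels)
  }
  list(data = cohort, map = new_discretization_map(entries))
}
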