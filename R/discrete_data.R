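# Internal integer-coded backend for discrete data.
#
# Learners and CI tests operate on an integer matrix (1-based level codes)
# plus per-column level vectors. Counting reduces to (weighted) tabulation
# on a mixed-radix configuration index. For repeated counting over the same
# data — bootstrap consensus in particular — rows are compressed to unique
# contingency cells with weights, making every count O(#cells) instead of
# O(n), and a bootstrap resample an equivalent multinomial draw over cells.

as_discrete_data <- function(data) {
  if (inherits(data, "exacnet_ddata")) return(data)
  stopifnot(is.data.frame(data))
  bad <- names(data)[!vapply(data, function(x) is.factor(x) || is.character(x) || is.logical(x), TRUE)]
  if (length(bad)) {
    stop2("column(s) %s are not discrete; discretize continuous predictors first (see discretize_hartemink() or fixed_clinical_cuts())",
          paste(sprintf("'%s'", bad), collapse = ", "), class = "exacnet_discrete_error")
  }
  cols <- lapply(data, function(x) if (is.factor(x)) x else factor(x))
  if (anyNA(data)) stop2("discrete data contain missing values; impute first")
  m <- vapply(cols, as.integer, integer(nrow(data)))
  if (nrow(data) == 1L) m <- matrix(m, nrow = 1L, dimnames = list(NULL, names(data)))
  levels <- lapply(cols, levels)
  structure(list(m = m, w = NULL, levels = levels,
                 nlev = vapply(levels, length, 1L),
                 nodes = names(data), n = nrow(data)),
            class = "exacnet_ddata")
}

# collapse rows into unique cells with weights (ncells <= prod(nlev))
compress_ddata <- function(dd) {
  if (!is.null(dd$w)) return(dd)
  ci <- config_index(dd, dd$nodes)
  cnt <- tabulate(ci$idx, nbins = ci$ncfg)
  keep <- which(cnt > 0L)
  # reconstruct cell coordinates from the mixed-radix index
  grid <- matrix(0L, length(keep), length(dd$nodes),
                 dimnames = list(NULL, dd$nodes))
  rem <- keep - 1L
  for (j in seq_along(dd$nodes)) {
    grid[, j] <- rem %% dd$nlev[j] + 1L
    rem <- rem %/% dd$nlev[j]
  }
  dd$m <- grid
  dd$w <- as.numeric(cnt[keep])
  dd
}

# multinomial bootstrap resample of a compressed dataset (identical in law
# to resampling m rows with replacement)
resample_ddata <- function(dd, m = dd$n) {
  stopifnot(!is.null(dd$w))
  w <- as.numeric(rmultinom(1L, m, dd$w))
  keep <- w > 0
  dd$m <- dd$m[keep, , drop = FALSE]
  dd$w <- w[keep]
  dd$n <- m
  # fresh shared memo for CI tests and family scores: the constraint-based
  # learners and both search phases revisit many identical computations on
  # the same replicate
  dd$cache <- new.env(parent = emptyenv())
  dd
}

ddata_subset_rows <- function(dd, idx) {
  stopifnot(is.null(dd$w))
  dd$m <- dd$m[idx, , drop = FALSE]
  dd$n <- length(idx)
  dd
}

# weighted tabulate: sum of w per index value in 1..nbins
wtabulate <- function(idx, w, nbins) {
  out <- numeric(nbins)
  agg <- rowsum(w, idx)
  out[as.integer(rownames(agg))] <- agg
  out
}

# 1-based mixed-radix configuration index over columns `cols` (may be empty)
config_index <- function(dd, cols) {
  if (!length(cols)) return(list(idx = rep(1L, nrow(dd$m)), ncfg = 1L))
  idx <- rep(1L, nrow(dd$m))
  stride <- 1L
  for (cc in cols) {
    idx <- idx + (dd$m[, cc] - 1L) * stride
    stride <- stride * dd$nlev[[cc]]
  }
  list(idx = idx, ncfg = stride)
}

# counts of `node` levels within each configuration of `cols`:
# matrix nlev(node) x ncfg
family_counts <- function(dd, node, cols) {
  ci <- config_index(dd, cols)
  nx <- dd$nlev[[node]]
  full <- dd$m[, node] + nx * (ci$idx - 1L)
  cnt <- if (is.null(dd$w)) tabulate(full, nbins = nx * ci$ncfg)
         else wtabulate(full, dd$w, nx * ci$ncfg)
  matrix(cnt, nrow = nx, ncol = ci$ncfg)
}
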