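# Adaptive synthetic oversampling (ADASYN) for class rebalancing, with
# SMOTE-NC-style handling of categorical features: synthetic rows
# interpolate numeric coordinates between a minority seed and one of its
# minority-class neighbours, and copy categorical values from the seed.

# numeric embedding for neighbour search: scaled numerics + one-hot factors
adasyn_embed <- function(features) {
  parts <- lapply(names(features), function(cn) {
    v <- features[[cn]]
    if (is.numeric(v)) {
      s <- sd(v); if (!is.finite(s) || s == 0) s <- 1
      matrix((v - mean(v)) / s, ncol = 1L)
    } else {
      f <- factor(v)
      m <- matrix(0, length(f), nlevels(f))
      m[cbind(seq_along(f), as.integer(f))] <- 1
      m
    }
  })
  do.call(cbind, parts)
}

# indices of the k nearest rows of `pool` for each row of `q` (self excluded
# when `self_idx` maps query rows into the pool)
knn_index <- function(q, pool, k, self_idx = NULL) {
  qn <- rowSums(q^2); pn <- rowSums(pool^2)
  out <- matrix(0L, nrow(q), k)
  chunk <- max(1L, floor(2e7 / max(nrow(pool), 1L)))
  for (s in seq(1L, nrow(q), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(q))
    d2 <- outer(qn[s:e], pn, "+") - 2 * q[s:e, , drop = FALSE] %*% t(pool)
    if (!is.null(self_idx)) {
      d2[cbind(seq_len(e - s + 1L), self_idx[s:e])] <- Inf
    }
    for (i in seq_len(e - s + 1L)) {
      out[s + i - 1L, ] <- order(d2[i, ])[seq_len(k)]
    }
  }
  out
}

#' ADASYN class rebalancing
#'
#' For each minority class, \eqn{G = (N_{maj} - N_{min}) \times ratio}
#' synthetic rows are generated. They are allocated across minority seeds
#' proportionally to the fraction of majority-class points among each
#' seed's `k_neighbors` nearest neighbours (the local density ratio, so
#' harder regions receive more synthesis), with largest-remainder rounding
#' so the total is exact. Numeric features are interpolated uniformly
#' between the seed and a random minority-class neighbour; categorical
#' features are copied from the seed. Original rows are preserved.
#'
#' @param features Data frame of fully observed features (numeric and/or
#'   factor columns).
#' @param labels Class labels (factor or coercible; >= 2 classes).
#' @param k_neighbors Neighbourhood size (default 5).
#' @param target_ratio Fraction of the majority-minority gap to close
#'   (default 1: full balance).
#' @param seed Integer seed.
#' @return List: `features`, `labels` (originals first, synthetic rows
#'   appended) and `n_synthetic` (named by class).
#' @export
adasyn_balance <- function(features, labels, k_neighbors = 5L, target_ratio = 1,
                           seed = 1L) {
  stopifnot(is.data.frame(features))
  labels <- factor(labels)
  if (anyNA(features)) stop2("ADASYN requires fully observed features")
  if (nlevels(labels) < 2L) stop2("at least 2 classes required")
  counts <- table(labels)
  maj <- names(counts)[which.max(counts)]
  minority <- setdiff(names(counts)[counts > 0], maj)
  emb <- adasyn_embed(features)
  is_num <- vapply(features, is.numeric, TRUE)
  synth <- list(); synth_lab <- character(0)
  n_syn <- setNames(integer(length(minority)), minority)
  withr::with_seed(seed, {
    for (cls in minority) {
      G <- round((counts[[maj]] - counts[[cls]]) * target_ratio)
      if (G <= 0) { n_syn[cls] <- 0L; next }
      idx <- which(labels == cls)
      if (length(idx) < k_neighbors + 1L) {
        stop2("minority class '%s' has %d members; needs at least k_neighbors + 1 = %d",
              cls, length(idx), k_neighbors + 1L)
      }
      nb_all <- knn_index(emb[idx, , drop = FALSE], emb, k_neighbors,
                          self_idx = idx)
      r <- rowMeans(matrix(labels[nb_all] == maj, nrow = length(idx)))
      if (sum(r) == 0) r <- rep(1, length(idx)) # isolated class: uniform allocation
      rh <- r / sum(r)
      g <- floor(rh * G)
      rem <- G - sum(g)
      if (rem > 0) {
        extra <- order(rh * G - g, decreasing = TRUE)[seq_len(rem)]
        g[extra] <- g[extra] + 1L
      }
      nb_min <- knn_index(emb[idx, , drop = FALSE], emb[idx, , drop = FALSE],
                          min(k_neighbors, length(idx) - 1L),
                          self_idx = seq_along(idx))
      for (i in which(g > 0)) {
        for (s in seq_len(g[i])) {
          nb <- idx[nb_min[i, sample.int(ncol(nb_min), 1L)]]
          lam <- runif(1)
          row <- features[idx[i], , drop = FALSE]
          for (cn in names(features)[is_num]) {
            row[[cn]] <- features[[cn]][idx[i]] +
              lam * (features[[cn]][nb] - features[[cn]][idx[i]])
          }
          synth[[length(synth) + 1L]] <- row
          synth_lab <- c(synth_lab, cls)
        }
      }
      n_syn[cls] <- sum(g)
    }
  })
  if (length(synth)) {
    features <- rbind(features, do.call(rbind, synth))
    labels <- factor(c(as.character(labels), synth_lab), levels = levels(labels))
  }
  rownames(features) <- NULL
  list(features = features, labels = labels, n_synthetic = n_syn)
}
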