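# Conditional independence testing for discrete variables.

#' G-squared conditional independence test
#'
#' Likelihood-ratio test of \eqn{X \perp Y \mid Z} for discrete variables:
#' \eqn{G^2 = 2 \sum O \ln(O/E)} accumulated within each configuration
#' (stratum) of the conditioning set, compared to a chi-square upper tail.
#' Degrees of freedom are \eqn{(|X|-1)(|Y|-1)} per stratum, with zero row or
#' column margins dropped from the stratum's contribution and strata with no
#' observations skipped entirely. A Pearson chi-square variant is available.
#'
#' @param x,y Names of the two tested variables.
#' @param conditioning_set Character vector of conditioning variable names
#'   (possibly empty).
#' @param data Data frame of factors (or internal discrete backend).
#' @param test `"g2"` (default, likelihood ratio) or `"x2"` (Pearson).
#' @return A list of class `exacnet_citest`: `statistic`,
#'   `degrees_of_freedom`, `p_value`, `test_name`, and `unreliable` (`TRUE`
#'   when the average cell count falls below 5 or all strata degenerate; the
#'   result is still returned).
#' @examples
#' d <- data.frame(x = factor(rep(c("a", "b"), each = 10)),
#'                 y = factor(rep(c("a", "b"), each = 10)))
#' g2_test("x", "y", character(0), d)$statistic # 40 * log(2)
#' @export
g2_test <- function(x, y, conditioning_set = character(0), data, test = c("g2", "x2")) {
  test <- match.arg(test)
  dd <- as_discrete_data(data)
  miss <- setdiff(c(x, y, conditioning_set), dd$nodes)
  if (length(miss)) stop2("unknown variable(s): %s", paste(miss, collapse = ", "))
  nx <- dd$nlev[[x]]; ny <- dd$nlev[[y]]
  w <- dd$w %||% rep(1, nrow(dd$m))
  res <- cpp_ci_stat(dd$m, w, match(x, dd$nodes) - 1L, match(y, dd$nodes) - 1L,
                     match(conditioning_set, dd$nodes) - 1L, unname(dd$nlev),
                     if (test == "x2") 1L else 0L)
  stat <- res[1]; df <- res[2]; nonempty <- res[3]
  df <- as.integer(df)
  unreliable <- FALSE
  if (df < 1L) {
    df <- 1L
    unreliable <- TRUE
  }
  if (dd$n / (nx * ny * max(nonempty, 1L)) < 5) unreliable <- TRUE
  structure(list(statistic = stat, degrees_of_freedom = df,
                 p_value = pchisq(stat, df = df, lower.tail = FALSE),
                 test_name = test, unreliable = unreliable),
            class = "exacnet_citest")
}

#' @export
print.exacnet_citest <- function(x, ...) {
  cat(sprintf("%s test: statistic = %.4f, df = %d, p = %.4g%s\n",
              toupper(x$test_name), x$statistic, x$degrees_of_freedom, x$p_value,
              if (x$unreliable) " (flagged unreliable)" else ""))
  invisible(x)
}


# internal fast path: p-value of the G2 test on a prepared backend, with an
# optional environment cache keyed by the canonical (x, y | S) triple
ci_pvalue <- function(dd, x, y, S = character(0), cache = NULL) {
  cache <- cache %||% dd$cache
  if (!is.null(cache)) {
    xy <- if (x < y) c(x, y) else c(y, x)
    key <- paste(xy[1], xy[2], paste(sort(S), collapse = ","), sep = "|")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
  }
  w <- dd$w %||% rep(1, nrow(dd$m))
  res <- cpp_ci_stat(dd$m, w, match(x, dd$nodes) - 1L, match(y, dd$nodes) - 1L,
                     match(S, dd$nodes) - 1L, unname(dd$nlev), 0L)
  p <- pchisq(res[1], df = max(res[2], 1), lower.tail = FALSE)
  if (!is.null(cache)) cache[[key]] <- p
  p
}
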