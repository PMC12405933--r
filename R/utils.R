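# Internal helpers: deterministic seed derivation, argument checks, logging.

#' Derive a stage seed from a pipeline seed
#'
#' All stochastic operations take an explicit seed. A single pipeline seed is
#' expanded into per-stage seeds with a fixed integer recurrence so that one
#' manifest entry suffices to reproduce every stage. Derived seeds stay below
#' 2^31 - 1.
#'
#' @param seed Integer master seed.
#' @param stage Character stage label (hashed into the derivation) or integer
#'   stage index.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (is.character(stage)) {
    stage <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  }
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  x <- (as.double(seed) %% m)
  # two rounds of a Lehmer-style mix keep stage streams well separated
  x <- (x * 48271 + as.double(stage) * 16807 + 12345) %% m
  x <- (x * 48271 + 7919) %% m
  as.integer(x %/% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(fmt, ..., class = "exacnet_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

assert_scalar_prob <- function(x, name, open_right = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && x >= 0 && (if (open_right) x < 1 else x <= 1)
  if (!ok) stop2("`%s` must be a single probability in [0,1%s)", name,
                 if (open_right) "" else "]")
  invisible(x)
}

# mode (most frequent level) of a factor/character vector, ties by level order
stat_mode <- function(x) {
  tab <- table(x)
  names(tab)[which.max(tab)]
}

log_stage <- function(verbose, stage, ...) {
  if (isTRUE(verbose)) {
    message(sprintf("[exacnet] %-12s %s", stage, sprintf(...)))
  }
  invisible(NULL)
}
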