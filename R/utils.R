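#' Round half away from zero
#'
#' Rounds to the nearest integer with ties going away from zero (the
#' "round-half-up" convention used when reporting integer percentages),
#' unlike [base::round()] which rounds half to even.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @examples
#' round_half_up(c(0.5, 1.5, 2.49, 87.99))
#' @export
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) stop(..., call. = FALSE)

#' Pooled-variance two-sample t test
#'
#' Classic Student's t with the pooled variance estimate and
#' df = n1 + n2 - 2. Unlike [stats::t.test()] this handles the degenerate
#' zero-within-group-variance case: equal means give t = 0, p = 1; a mean
#' shift gives t = +/-Inf and p = 0 (below the machine floor) rather than
#' an error.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param conf_level confidence level for the per-group t-intervals.
#' @return list with `t`, `df`, `p`, per-group means, and per-group
#'   `conf_level` t-interval half-widths (`ci_x`, `ci_y`).
#' @examples
#' pooled_t_test(c(1, 2, 3), c(4, 5, 6))
#' @export
pooled_t_test <- function(x, y, conf_level = 0.95) {
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2)
    stop_domain("pooled t test needs >= 2 observations per group")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / df
  d <- mean(x) - mean(y)
  if (sp2 == 0) {
    tval <- if (d == 0) 0 else sign(d) * Inf
    p <- if (d == 0) 1 else 0
  } else {
    tval <- d / sqrt(sp2 * (1 / n1 + 1 / n2))
    p <- 2 * stats::pt(-abs(tval), df)
  }
  tq <- function(n) if (n > 1) stats::qt(1 - (1 - conf_level) / 2, n - 1) else NA_real_
  list(
    t = tval, df = df, p = p,
    mean_x = mean(x), mean_y = mean(y),
    ci_x = tq(n1) * stats::sd(x) / sqrt(n1),
    ci_y = tq(n2) * stats::sd(y) / sqrt(n2)
  )
}

# derive a stream seed from a master seed, keeping within 32-bit range
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 104729L * as.integer(offset)) %% 2147483647L
}
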