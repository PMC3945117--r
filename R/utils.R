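#' @import data.table
#' @importFrom stats as.dist coef cor cutree dist dnorm hclust lm.fit
#'   pf qt rbinom rnorm rpois runif setNames fisher.test quantile median sd
#' @importFrom utils head tail packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Base R `round()` rounds half to even; the strand-shift rule needs
#' 99.5 -> 100. Vectorized.
#' @param x numeric
#' @return numeric, rounded with ties going away from zero
#' @keywords internal
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Wrap hours onto the 24-h circle
#' @param h numeric hours
#' @param centered if TRUE wrap into (-12, 12] instead of [0, 24)
#' @return wrapped hours
#' @export
wrap24 <- function(h, centered = FALSE) {
  h <- h %% 24
  if (centered) h <- ifelse(h > 12, h - 24, h)
  h
}

wrap_pi <- function(a) {
  a <- a %% (2 * pi)
  ifelse(a > pi, a - 2 * pi, a)
}

#' Circular correlation of two phase vectors (Fisher-Lee)
#'
#' @param a,b phases in hours on a common `period`-hour circle
#' @param period circle period in hours (default 24)
#' @return correlation coefficient in [-1, 1]
#' @export
circular_cor <- function(a, b, period = 24) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  ta <- a * 2 * pi / period
  tb <- b * 2 * pi / period
  num <- 0; da <- 0; db <- 0
  n <- length(ta)
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    num <- num + sum(sin(ta[i] - ta[j]) * sin(tb[i] - tb[j]))
    da <- da + sum(sin(ta[i] - ta[j])^2)
    db <- db + sum(sin(tb[i] - tb[j])^2)
  }
  if (da == 0 || db == 0) return(NA_real_)
  num / sqrt(da * db)
}

# derive a 32-bit-safe child seed from a master seed and a stream index
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483629L)
}

stop_if_not_cols <- function(dt, cols, what) {
  miss <- setdiff(cols, names(dt))
  if (length(miss))
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
}
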