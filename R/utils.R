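# internal validation helpers

check_freq <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    stop("`", name, "` must be a single finite number in [0, 1], got ",
         deparse(substitute(x)), " = ", format(x), call. = FALSE)
  }
  as.numeric(x)
}

check_finite <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("`", name, "` must be a single finite number.", call. = FALSE)
  }
  as.numeric(x)
}

#' Round half away from zero
#'
#' Display rounding used for reported variance components. Unlike [round()],
#' which rounds half to even, exact halves move away from zero, so 0.125
#' becomes 0.13 at two decimals. Used only at the output layer; all
#' inter-module arithmetic is full precision.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2).
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(0.125, 0.0625), 2)
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# weighted mean / variance with weights summing to 1
wmean <- function(x, w) sum(w * x)
wvar <- function(x, w) {
  mu <- sum(w * x)
  sum(w * (x - mu)^2)
}
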