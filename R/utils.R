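## Small numerical helpers shared across modules.

#' Wrap angles to the interval (-pi, pi]
#'
#' @param theta numeric vector of angles in radians.
#' @return angles wrapped to (-pi, pi].
#' @export
wrap_angle <- function(theta) {
  out <- theta - 2 * pi * floor((theta + pi) / (2 * pi))
  # floor() maps pi to -pi; the convention here keeps +pi
  out[out <= -pi] <- out[out <= -pi] + 2 * pi
  out
}

#' Minimum-image angular difference
#'
#' Signed difference a - b taken the short way around the circle.
#'
#' @param a,b angles in radians.
#' @return differences in (-pi, pi].
#' @export
angle_diff <- function(a, b) wrap_angle(a - b)

#' Convert degrees to radians
#' @param x angles in degrees.
#' @export
deg2rad <- function(x) x * pi / 180

#' Convert radians to degrees
#' @param x angles in radians.
#' @export
rad2deg <- function(x) x * 180 / pi

#' Circular mean of angles
#' @param theta angles in radians.
#' @return mean direction in (-pi, pi].
#' @export
circular_mean <- function(theta) atan2(mean(sin(theta)), mean(cos(theta)))

#' Block-averaged standard error of the mean
#'
#' Splits the series into contiguous blocks of `block_len` observations and
#' uses the spread of block means to estimate the standard error, which is
#' robust to serial correlation within blocks.
#'
#' @param x numeric series.
#' @param block_len block length in observations; the series must hold at
#'   least two full blocks.
#' @return standard error of mean(x).
#' @export
block_se <- function(x, block_len = 100L) {
  n <- length(x)
  n_blocks <- n %/% block_len
  if (n_blocks < 2L) {
    stop("block_se: need at least 2 full blocks (", n, " obs, block_len ",
         block_len, ")")
  }
  used <- n_blocks * block_len
  bm <- colMeans(matrix(x[seq_len(used)], nrow = block_len))
  sd(bm) / sqrt(n_blocks)
}

## strictly internal ---------------------------------------------------------

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.is_count <- function(x) is.numeric(x) && length(x) == 1L && x >= 1 &&
  x == floor(x)

# mix a user seed with a small stage tag, staying inside 32-bit range
.derive_seed <- function(seed, tag) {
  (as.integer(seed) * 1009L + as.integer(tag)) %% 2147483647L
}
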