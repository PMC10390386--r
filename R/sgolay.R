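# Savitzky-Golay smoothing.
#
# The filter is the closed-form least-squares fit of a degree-`order`
# polynomial over a sliding window: the smoothed value is the fitted
# polynomial evaluated at the window center, which reduces to a fixed
# convolution in the interior. Window edges use the corresponding rows of the
# projection matrix (a polynomial fit to the first/last `frame` points), as in
# the classical formulation. Exactly preserves polynomials up to `order`.

#' Savitzky-Golay filter
#'
#' @param y numeric vector (no missing values).
#' @param frame odd window length (default 9).
#' @param order polynomial order (default 4), `order < frame`.
#' @return smoothed vector of the same length.
#' @export
#' @examples
#' sgolay_filter(sin(seq(0, 1, length.out = 50)))
sgolay_filter <- function(y, frame = 9L, order = 4L) {
  frame <- as.integer(frame)
  order <- as.integer(order)
  if (frame %% 2L != 1L) stop("`frame` must be odd")
  if (order >= frame) stop("`order` must be < `frame`")
  n <- length(y)
  if (anyNA(y)) stop("`y` must not contain missing values")
  if (n < frame) return(y)
  half <- (frame - 1L) %/% 2L
  A <- outer(seq_len(frame) - half - 1L, 0:order, `^`)
  # projection onto the polynomial space: H = A (A'A)^-1 A'
  H <- A %*% solve(crossprod(A), t(A))
  out <- numeric(n)
  center <- H[half + 1L, ]
  for (i in seq((half + 1L), (n - half))) {
    out[i] <- sum(center * y[(i - half):(i + half)])
  }
  out[1:half] <- H[1:half, ] %*% y[1:frame]
  out[(n - half + 1L):n] <- H[(half + 2L):frame, ] %*% y[(n - frame + 1L):n]
  out
}
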