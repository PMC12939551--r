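# Total-time-on-test transform, the standard graphical aging diagnostic.

#' Total-time-on-test (TTT) transform
#'
#' Computes the scaled TTT curve of a sample: with normalized spacings
#' \eqn{D_k = (N - k + 1)(X_{k:N} - X_{k-1:N})} (and \eqn{X_{0:N} = 0})
#' and partial sums \eqn{S_i = \sum_{k \le i} D_k}, the curve is the set
#' of points \eqn{(i/N,\; S_i/S_N)} for \eqn{i = 1, \dots, N}.  The last
#' partial sum telescopes to \eqn{S_N = \sum_i X_i}.  For exponential data
#' the curve hugs the unit-square diagonal; concave curves above the
#' diagonal indicate IFR (hence IFRA) aging, convex curves below it DFR
#' behaviour.  The scaled curve is invariant under rescaling of the data.
#'
#' @param x Non-negative lifetimes (at least one positive) or a
#'   [lifetime_sample()].
#' @return A `data.frame` of class `"ttt_curve"` with columns `i`, `u`
#'   (= i/N), `ttt` (= S_i/S_N), plus attributes `S` and `D` holding the
#'   raw partial sums and spacings.
#' @examples
#' ttt_transform(c(1, 2, 3))   # points (1/3, 1/2), (2/3, 5/6), (1, 1)
#' @export
ttt_transform <- function(x) {
  s <- .as_sample(x)
  N <- s$n
  D <- (N - seq_len(N) + 1) * diff(c(0, s$sorted))
  S <- cumsum(D)
  out <- data.frame(i = seq_len(N), u = seq_len(N) / N, ttt = S / S[N])
  attr(out, "S") <- S
  attr(out, "D") <- D
  class(out) <- c("ttt_curve", "data.frame")
  out
}

#' Plot a TTT curve
#'
#' Draws the scaled TTT curve with the exponential reference diagonal.
#'
#' @param x A `"ttt_curve"` from [ttt_transform()].
#' @param ... Passed to [plot()].
#' @export
plot.ttt_curve <- function(x, ...) {
  plot(c(0, x$u), c(0, x$ttt), type = "l", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "i/N", ylab = expression(S[i] / S[N]), ...)
  graphics::abline(0, 1, lty = 2, col = "red")
  invisible(x)
}
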