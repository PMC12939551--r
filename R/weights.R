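# Signed L-statistic weight functions J1 and J2.
#
# Both weights arise from comparing the cumulative extropy of a series-system
# lifetime X_{1:n} with that of its proportional-(reversed-)hazards transform
# with exponent b.  They vanish identically in the limit b -> 1 and integrate
# the departure-from-exponentiality signal across the probability scale.

# power with the boundary convention 0^0 = 1; strictly negative exponents at
# base 0 are the caller's responsibility (they signal a violated regularity
# condition).  Very small positive bases go through log-space.
.pow <- function(base, expo) {
  out <- base^expo
  tiny <- base > 0 & base < 1e-12
  if (any(tiny)) out[tiny] <- exp(expo[tiny] * log(base[tiny]))
  zz <- base == 0 & expo == 0
  out[zz] <- 1
  out
}

.check_tuning <- function(n, b, which = 1) {
  if (length(n) != 1L || !is.finite(n) || n < 1 || n != round(n))
    stop("`n` must be a single integer >= 1", call. = FALSE)
  if (length(b) != 1L || !is.finite(b) || b <= 0 || b >= 1)
    stop("`b` must be a single number in (0, 1)", call. = FALSE)
  min_nb <- if (which == 1) 0.25 else 0.5
  if (n * b < min_nb)
    stop(sprintf("tuning (n = %s, b = %s) violates the regularity condition nb >= %s for the delta-%d statistic",
                 n, b, min_nb, which), call. = FALSE)
  invisible(list(n = as.integer(n), b = b))
}

#' Tuning parameters for the cumulative-extropy tests
#'
#' Validates the pair (`n`, `b`) indexing an extropy test statistic: `n` is
#' the integer order-statistic parameter of the series system and `b` the
#' proportional-hazards scaling parameter in (0, 1).  The asymptotic theory
#' requires `n * b >= 1/4` for the first (cumulative residual extropy) family
#' and `n * b >= 1/2` for the second (cumulative past extropy) family.
#'
#' @param n Positive integer order-statistic parameter.
#' @param b Scaling parameter, `0 < b < 1`.
#' @param which Which statistic family the pair will be used with (`1` or
#'   `2`); controls which regularity bound is enforced.
#' @return A list with elements `n` and `b`, invisibly classed as
#'   `"tuning_params"`.
#' @examples
#' tuning_params(1, 0.5)
#' tuning_params(2, 0.7, which = 2)
#' @export
tuning_params <- function(n, b, which = 1) {
  p <- .check_tuning(n, b, which)
  structure(p, class = "tuning_params")
}

#' Weight functions of the extropy-based L-statistics
#'
#' `j1_weight()` evaluates
#' \deqn{J_1(u) = n\left[(1-u)^{2n-1} - b^2 (1-u)^{2nb-1}\right]}
#' and `j2_weight()` evaluates
#' \deqn{J_2(u) = n\left[(1-u)^{n-1} - (1-u)^{2n-1}
#'   - b^2\left\{(1-u)^{nb-1} - (1-u)^{2nb-1}\right\}\right],}
#' the signed weights applied to the order statistics in the two deviation
#' measures.  At `u = 1` any exponent equal to zero is evaluated with the
#' convention `0^0 = 1` (needed e.g. for `n = 1, b = 0.5`, where
#' `2nb - 1 = 0`); a strictly negative exponent at `u = 1` is a domain error
#' because the corresponding regularity condition fails at the boundary.
#'
#' `j1_envelope()` and `j2_envelope()` return the pointwise bounds
#' \eqn{2n(1-u)^{2nb-1}} and \eqn{2n(1-u)^{nb-1}} that dominate the absolute
#' weights on `[0, 1)`; they are used in property checks of the asymptotic
#' regularity conditions.
#'
#' @param u Evaluation points in `[0, 1]` (the probability scale).
#' @param n,b Tuning parameters, see [tuning_params()].
#' @return Numeric vector of weight (or envelope) values, same length as `u`.
#' @examples
#' j1_weight(0, n = 1, b = 0.5)            # 0.75
#' j1_weight(0.5, n = 2, b = 0.5)          # 0
#' j2_weight(0, n = 2, b = 0.7)            # 0
#' @export
j1_weight <- function(u, n, b) {
  .check_tuning(n, b, which = 1)
  if (any(u < 0 | u > 1)) stop("`u` must lie in [0, 1]", call. = FALSE)
  e2 <- 2 * n * b - 1
  if (e2 < 0 && any(u == 1))
    stop("J1 is unbounded at u = 1 when 2nb - 1 < 0 (regularity condition violated)",
         call. = FALSE)
  n * (.pow(1 - u, rep_len(2 * n - 1, length(u))) -
         b^2 * .pow(1 - u, rep_len(e2, length(u))))
}

#' @rdname j1_weight
#' @export
j2_weight <- function(u, n, b) {
  .check_tuning(n, b, which = 2)
  if (any(u < 0 | u > 1)) stop("`u` must lie in [0, 1]", call. = FALSE)
  e3 <- n * b - 1
  if (e3 < 0 && any(u == 1))
    stop("J2 is unbounded at u = 1 when nb - 1 < 0 (regularity condition violated)",
         call. = FALSE)
  len <- length(u)
  n * (.pow(1 - u, rep_len(n - 1, len)) - .pow(1 - u, rep_len(2 * n - 1, len)) -
         b^2 * (.pow(1 - u, rep_len(e3, len)) -
                  .pow(1 - u, rep_len(2 * n * b - 1, len))))
}

#' @rdname j1_weight
#' @export
j1_envelope <- function(u, n, b) {
  .check_tuning(n, b, which = 1)
  if (any(u < 0 | u >= 1)) stop("`u` must lie in [0, 1)", call. = FALSE)
  2 * n * (1 - u)^(2 * n * b - 1)
}

#' @rdname j1_weight
#' @export
j2_envelope <- function(u, n, b) {
  .check_tuning(n, b, which = 2)
  if (any(u < 0 | u >= 1)) stop("`u` must lie in [0, 1)", call. = FALSE)
  2 * n * (1 - u)^(n * b - 1)
}
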