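# Monte Carlo calibration engine: null critical values, empirical power and
# power-table grids over the standard lifetime alternatives.

#' Test-statistic specification for the Monte Carlo engine
#'
#' Packages one scale-invariant statistic (an extropy statistic or a
#' competitor) as a function of a sample, together with a printable label,
#' for use by [critical_values()], [empirical_power()] and
#' [reproduce_power_table()].
#'
#' @param name `"delta1"`, `"delta2"`, `"deshpande"`, `"aly"` or `"tn"`.
#' @param n,b Tuning parameters for the extropy statistics.
#' @param a,c Tuning parameters for the competitors (`a` in (0,1) for
#'   Deshpande, `a > 1` and `c > 0` for Aly).
#' @return A list of class `"ifra_statistic"` with fields `label` and `fn`
#'   (a function mapping a numeric sample to the statistic value).
#' @examples
#' st <- ifra_statistic("delta1", n = 1, b = 0.5)
#' st$fn(rexp(25))
#' @export
ifra_statistic <- function(name = c("delta1", "delta2", "deshpande", "aly", "tn"),
                           n = 1, b = 0.5, a = NULL, c = NULL) {
  name <- match.arg(name)
  switch(name,
         delta1 = {
           .check_tuning(n, b, 1)
           structure(list(label = sprintf("delta1*(%d,%g)", n, b),
                          fn = function(x) delta_star(x, n, b, which = 1)),
                     class = "ifra_statistic")
         },
         delta2 = {
           .check_tuning(n, b, 2)
           structure(list(label = sprintf("delta2*(%d,%g)", n, b),
                          fn = function(x) delta_star(x, n, b, which = 2)),
                     class = "ifra_statistic")
         },
         deshpande = {
           if (is.null(a)) a <- 0.5
           structure(list(label = sprintf("J(%g)", a),
                          fn = function(x) deshpande_J(x, a = a)),
                     class = "ifra_statistic")
         },
         aly = {
           if (is.null(a)) a <- 3
           if (is.null(c)) c <- 0.5
           structure(list(label = sprintf("t1(%g,%g)", a, c),
                          fn = function(x) aly_t1(x, a = a, c = c)),
                     class = "ifra_statistic")
         },
         tn = structure(list(label = "TN", fn = jammalamadaka_TN),
                        class = "ifra_statistic"))
}

# evaluate a statistic on every row of a samples matrix
.batch_stat <- function(statistic, X) {
  vapply(seq_len(nrow(X)), function(i) statistic$fn(X[i, ]), numeric(1))
}

#' Empirical null critical values
#'
#' Simulates `reps` standard-exponential samples of size `N` (sufficient for
#' any exponential null by scale invariance of every statistic in the
#' package), evaluates the statistic on each, and returns the empirical
#' upper quantiles used as rejection thresholds.  Quantiles use linear
#' interpolation of order statistics (`type = 7`), recorded in the output.
#'
#' @param statistic An [ifra_statistic()].
#' @param N Sample size.
#' @param alpha Significance level(s); the returned quantiles are at
#'   `1 - alpha`.
#' @param reps Number of null replicates (10000 in the reference power
#'   study; at least 1000 recommended).
#' @param seed Integer seed (required: calibration must be reproducible).
#' @return A list of class `"critical_values"` with the quantiles and full
#'   calibration metadata.
#' @examples
#' st <- ifra_statistic("tn")
#' critical_values(st, N = 25, reps = 500, seed = 1)
#' @export
critical_values <- function(statistic, N, alpha = 0.05, reps = 10000, seed) {
  stopifnot(inherits(statistic, "ifra_statistic"))
  if (missing(seed)) stop("an explicit `seed` is required", call. = FALSE)
  set.seed(seed)
  X <- matrix(stats::rexp(reps * N), nrow = reps)
  stats_null <- .batch_stat(statistic, X)
  q <- stats::quantile(stats_null, 1 - alpha, names = FALSE, type = 7)
  structure(list(statistic = statistic$label, N = as.integer(N),
                 alpha = alpha, reps = as.integer(reps), seed = seed,
                 quantile = q, quantile_type = 7L),
            class = "critical_values")
}

#' @export
print.critical_values <- function(x, ...) {
  cat(sprintf("Null critical values for %s at N = %d (%d replicates, seed %s)\n",
              x$statistic, x$N, x$reps, format(x$seed)))
  for (k in seq_along(x$alpha))
    cat(sprintf("  alpha = %-6g quantile = %.6g\n", x$alpha[k], x$quantile[k]))
  invisible(x)
}

#' Empirical power against a lifetime alternative
#'
#' Estimates the rejection probability of a Monte Carlo-calibrated test:
#' the proportion of `reps` samples from `model` whose statistic exceeds
#' the null critical value.
#'
#' @param statistic An [ifra_statistic()].
#' @param model A [lifetime_model()] alternative.
#' @param N Sample size.
#' @param alpha Significance level; must be among the levels the critical
#'   values were computed at.
#' @param reps Number of alternative-model replicates.
#' @param seed Integer seed for the alternative draws.
#' @param critvals A [critical_values()] object for the same statistic,
#'   `N` and level (recomputed per `N`: size-correct comparisons across
#'   sample sizes need per-`N` calibration).
#' @return The rejection proportion (a single number in `[0, 1]`).
#' @export
empirical_power <- function(statistic, model, N, alpha = 0.05, reps = 10000,
                            seed, critvals) {
  stopifnot(inherits(statistic, "ifra_statistic"),
            inherits(model, "lifetime_model"),
            inherits(critvals, "critical_values"))
  if (missing(seed)) stop("an explicit `seed` is required", call. = FALSE)
  if (critvals$statistic != statistic$label || critvals$N != N)
    stop("`critvals` were computed for a different statistic or sample size",
         call. = FALSE)
  k <- match(alpha, critvals$alpha)
  if (is.na(k))
    stop("`critvals` do not include level alpha = ", alpha, call. = FALSE)
  crit <- critvals$quantile[k]
  set.seed(seed)
  X <- matrix(rlifetime(model, reps * N), nrow = reps)
  mean(.batch_stat(statistic, X) > crit)
}

#' Reproduce a power-comparison grid
#'
#' Runs the full power comparison of the nine reference statistics (six
#' extropy settings and three competitors) over the four alternative
#' families at one sample size, using per-`N` Monte Carlo critical values.
#' With `reps = 10000` this matches the design of the reference power
#' study; smaller `reps` give a faster smoke-mode grid with the same
#' qualitative ordering.
#'
#' @param N Sample size (25, 50 and 100 in the reference study).
#' @param reps Replicates for both calibration and power.
#' @param seed Master integer seed; per-(statistic, family, theta) streams
#'   are derived deterministically from it.
#' @param thetas Aging-parameter grid per family.
#' @param statistics Optional named list of [ifra_statistic()] objects;
#'   defaults to the nine reference statistics.
#' @return A `data.frame` with columns `family`, `theta`, `N`, `statistic`,
#'   `power`, `reps`, `seed` (CSV-exportable).
#' @export
reproduce_power_table <- function(N, reps = 10000, seed,
                                  thetas = c(1.2, 1.5, 2, 2.5, 3),
                                  statistics = NULL) {
  if (missing(seed)) stop("an explicit `seed` is required", call. = FALSE)
  if (is.null(statistics)) statistics <- reference_statistics()
  families <- c("lfr", "makeham", "gamma", "weibull")
  out <- list()
  row <- 0L
  for (si in seq_along(statistics)) {
    st <- statistics[[si]]
    cv <- critical_values(st, N, alpha = 0.05, reps = reps,
                          seed = seed + 1000L * si)
    for (fam in families) {
      for (th in thetas) {
        row <- row + 1L
        sub_seed <- seed + 1000L * si +
          10L * match(fam, families) + match(th, thetas)
        pw <- empirical_power(st, lifetime_model(fam, th), N,
                              alpha = 0.05, reps = reps,
                              seed = sub_seed, critvals = cv)
        out[[row]] <- data.frame(family = fam, theta = th, N = N,
                                 statistic = st$label, power = pw,
                                 reps = reps, seed = seed)
      }
    }
  }
  do.call(rbind, out)
}

#' The nine statistics of the reference power study
#'
#' Three competitors (Deshpande `J(0.5)`, Aly `t1(3, 0.5)`,
#' Jammalamadaka `TN`) and six extropy settings
#' (`delta1*` at `(n, b) = (1, 0.5), (1, 0.7), (1, 0.8)`;
#' `delta2*` at `(2, 0.7), (2, 0.8), (4, 0.5)`).
#'
#' @return A named list of [ifra_statistic()] objects.
#' @export
reference_statistics <- function() {
  list(J0.5 = ifra_statistic("deshpande", a = 0.5),
       t1 = ifra_statistic("aly", a = 3, c = 0.5),
       TN = ifra_statistic("tn"),
       d1_1_05 = ifra_statistic("delta1", n = 1, b = 0.5),
       d1_1_07 = ifra_statistic("delta1", n = 1, b = 0.7),
       d1_1_08 = ifra_statistic("delta1", n = 1, b = 0.8),
       d2_2_07 = ifra_statistic("delta2", n = 2, b = 0.7),
       d2_2_08 = ifra_statistic("delta2", n = 2, b = 0.8),
       d2_4_05 = ifra_statistic("delta2", n = 4, b = 0.5))
}
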