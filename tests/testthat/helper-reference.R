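# Published worked-example statistics for the four packaged datasets
# (rows: statistic, columns: dataset 1..4).
published_statistics <- local({
  m <- rbind(
    J0.5    = c(0.6983, 0.7422, 0.9144, 0.6977),
    t1      = c(0.8945, 0.8666, 0.9798, 0.8820),
    TN      = c(0.7289, 0.7516, 0.8603, 0.7160),
    d1_1_05 = c(0.0198, 0.0659, 0.1609, 0.0300),
    d1_1_07 = c(0.0238, 0.0385, 0.0947, 0.0193),
    d1_1_08 = c(0.0147, 0.0239, 0.0617, 0.0114),
    d2_2_07 = c(0.0225, 0.0546, 0.1172, 0.0297),
    d2_2_08 = c(0.0133, 0.0334, 0.0765, 0.0170),
    d2_4_05 = c(0.0336, 0.0539, 0.1608, 0.0266)
  )
  colnames(m) <- paste0("ds", 1:4)
  m
})

# evaluate all nine reference statistics on one sample, in the same order
# as the rows of published_statistics (data kept in given order for t1)
all_reference_stats <- function(x) {
  c(J0.5    = deshpande_J(x, a = 0.5),
    t1      = aly_t1(x, a = 3, c = 0.5),
    TN      = jammalamadaka_TN(x),
    d1_1_05 = delta_star(x, 1, 0.5, which = 1),
    d1_1_07 = delta_star(x, 1, 0.7, which = 1),
    d1_1_08 = delta_star(x, 1, 0.8, which = 1),
    d2_2_07 = delta_star(x, 2, 0.7, which = 2),
    d2_2_08 = delta_star(x, 2, 0.8, which = 2),
    d2_4_05 = delta_star(x, 4, 0.5, which = 2))
}

# independent weight-function evaluations used by brute-force oracles
# (kept separate from the package implementation on purpose)
oracle_j1 <- function(u, n, b) {
  p1 <- if (1 - u == 0 && 2 * n - 1 == 0) 1 else (1 - u)^(2 * n - 1)
  p2 <- if (1 - u == 0 && 2 * n * b - 1 == 0) 1 else (1 - u)^(2 * n * b - 1)
  n * (p1 - b^2 * p2)
}
oracle_j2 <- function(u, n, b) {
  pw <- function(base, e) if (base == 0 && e == 0) 1 else base^e
  n * (pw(1 - u, n - 1) - pw(1 - u, 2 * n - 1) -
         b^2 * (pw(1 - u, n * b - 1) - pw(1 - u, 2 * n * b - 1)))
}
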