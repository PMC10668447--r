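# Independent oracles and small builders shared across tests.
# Oracles are deliberately written with different algorithms than the
# package (brute-force interpolation, full enumeration) so agreement is
# meaningful.

# linear-interpolation (type 7) quantile, written from the definition:
# the p-quantile sits at position h = (n - 1) p + 1 of the sorted sample
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

oracle_fences <- function(x, k = 1.5) {
  q1 <- oracle_quantile(x, 0.25)
  q3 <- oracle_quantile(x, 0.75)
  c(lower = q1 - k * (q3 - q1), upper = q3 + k * (q3 - q1))
}

# full-enumeration two-sided permutation p for the rank-sum test
oracle_rank_sum_p <- function(x, y) {
  n <- length(x)
  N <- n + length(y)
  r <- rank(c(x, y))
  cmb <- utils::combn(N, n)
  ws <- colSums(matrix(r[cmb], nrow = n))
  mu <- n * (N + 1) / 2
  mean(abs(ws - mu) >= abs(sum(r[seq_len(n)]) - mu) - 1e-9)
}

# full sign-grid two-sided p for the signed-rank test
oracle_signed_rank_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  r <- rank(abs(d))
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.numeric(signs %*% r)
  mu <- sum(r) / 2
  mean(abs(vs - mu) >= abs(sum(r[d > 0]) - mu) - 1e-9)
}

# closed-form 2x2 Pearson chi-square
oracle_chisq_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# one-way ANOVA F on absolute deviations from group medians, via lm()
oracle_levene <- function(x, y) {
  dev <- c(abs(x - median(x)), abs(y - median(y)))
  grp <- factor(rep(1:2, c(length(x), length(y))))
  stats::anova(stats::lm(dev ~ grp))[["F value"]][1]
}

# a deliberately small game for simulation-heavy tests: one axes level,
# reduced tracking rate agents keep runtimes modest
mini_game <- function(minutes = 0.25) {
  game_config(list(level_config("axes", c(12.5, 25, 37.5, 50), 2L, minutes)))
}

fast_agent <- function(...) {
  agent_params(frame_rate = 5, ...)
}

# unbiased cohort generators with mild dwell heterogeneity only
null_control_gen <- function(i) fast_agent(base_dwell = 0.35 * runif(1, 0.8, 1.3))
null_patient_gen <- function(i) fast_agent(base_dwell = 0.35 * runif(1, 0.9, 1.6))
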