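#' Group-level nonparametric statistics
#'
#' Nonparametric comparisons used at the cohort level: a chi-square test on
#' typicality counts, Wilcoxon rank-sum and signed-rank tests for
#' midpoints, and Levene's test (median-centred, i.e. the Brown-Forsythe
#' variant) for variance homogeneity. No multiple-testing correction is
#' applied.
#'
#' @name group-stats
NULL

#' Tabulate typicality counts by group
#'
#' Sums Booleans across players and metrics into a 2 x 2 contingency table
#' (rows patients/controls, columns atypical/typical), excluding missing
#' cells. The counting grain is configurable:
#'
#' * `"boolean"` (default) — the finest available Boolean: one count per
#'   player x metric x level for per-level metrics, per player x metric for
#'   pooled scores.
#' * `"cell"` — one count per summary-matrix cell, a cell counting as
#'   atypical when its proportion exceeds zero.
#'
#' @param matrix An `atypicality_matrix` from [build_summary_matrix()].
#' @param grain `"boolean"` or `"cell"`.
#' @return A 2 x 2 integer matrix with dimnames
#'   `list(group = c("patient", "control"), c("atypical", "typical"))`.
#' @export
typicality_counts <- function(matrix, grain = c("boolean", "cell")) {
  stopifnot(inherits(matrix, "atypicality_matrix"))
  grain <- match.arg(grain)
  if (grain == "boolean") {
    fl <- matrix$flags[!is.na(matrix$flags$flag), , drop = FALSE]
    grp <- fl$group
    atyp <- fl$flag
  } else {
    v <- matrix$values
    keep <- !is.na(v)
    grp <- matrix(rep(unname(matrix$groups[rownames(v)]), ncol(v)), nrow = nrow(v))[keep]
    atyp <- v[keep] > 0
  }
  out <- rbind(
    patient = c(sum(atyp[grp == "patient"]), sum(!atyp[grp == "patient"])),
    control = c(sum(atyp[grp == "control"]), sum(!atyp[grp == "control"]))
  )
  colnames(out) <- c("atypical", "typical")
  storage.mode(out) <- "integer"
  out
}

#' Pearson chi-square test on a 2 x 2 table
#'
#' Uncorrected Pearson chi-square (no Yates continuity correction by
#' default), 1 degree of freedom.
#'
#' @param table 2 x 2 matrix of non-negative counts.
#' @param correct Apply Yates continuity correction.
#' @return List: `statistic`, `p`, `df`, `n`.
#' @export
chisq_2x2 <- function(table, correct = FALSE) {
  stopifnot(is.matrix(table), all(dim(table) == 2), all(table >= 0), sum(table) > 0)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("chi-square is undefined for a table with a zero margin", call. = FALSE)
  }
  # small-sample approximation caveats are documented, not warned
  ct <- suppressWarnings(stats::chisq.test(table, correct = correct))
  list(
    statistic = unname(ct$statistic), p = ct$p.value,
    df = unname(ct$parameter), n = sum(table)
  )
}

# exact permutation distribution of a fixed-size subset sum over integer
# "scores" (2 x midranks), via dynamic programming; returns the two-sided
# tail probability P(|S - E S| >= |observed - E S|)
subset_sum_tail_p <- function(scores, n_subset, observed) {
  total <- sum(scores)
  smax <- total
  # dp[k + 1, s + 1] = number of size-k subsets with sum s
  dp <- matrix(0, nrow = n_subset + 1, ncol = smax + 1)
  dp[1, 1] <- 1
  for (sc in scores) {
    kmax <- n_subset
    for (k in kmax:1) {
      nz <- which(dp[k, ] > 0)
      if (length(nz)) dp[k + 1, nz + sc] <- dp[k + 1, nz + sc] + dp[k, nz]
    }
  }
  counts <- dp[n_subset + 1, ]
  sums <- 0:smax
  mu <- n_subset * total / length(scores)
  tail <- abs(sums - mu) >= abs(observed - mu) - 1e-9
  sum(counts[tail]) / sum(counts)
}

# exact distribution of the positive-part sum over all sign assignments
sign_sum_tail_p <- function(scores, observed) {
  smax <- sum(scores)
  dp <- numeric(smax + 1)
  dp[1] <- 1
  for (sc in scores) {
    nz <- which(dp > 0)
    new <- dp
    new[nz + sc] <- new[nz + sc] + dp[nz]
    dp <- new
  }
  sums <- 0:smax
  mu <- smax / 2
  tail <- abs(sums - mu) >= abs(observed - mu) - 1e-9
  sum(dp[tail]) / sum(dp)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Midrank ties throughout. The reported `rank_sum` is the sum of ranks of
#' `x` in the combined sample; `statistic` is the standardised
#' (tie-corrected) normal deviate of that rank sum, the convention used
#' when quoting `W` values near 2 for cohort-sized samples. The two-sided
#' p-value is the exact tie-aware permutation probability
#' `P(|W - E W| >= |w_obs - E W|)` when the combined sample has at most
#' `exact_limit` observations, else the normal approximation with tie
#' correction.
#'
#' @param x,y Numeric samples.
#' @param exact_limit Largest combined sample size for which the exact
#'   permutation distribution is used (default 40).
#' @return List: `rank_sum`, `statistic` (z), `p`, `method`, `n_x`, `n_y`.
#' @export
rank_sum_test <- function(x, y, exact_limit = 40) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  stopifnot(length(x) > 0, length(y) > 0)
  nx <- length(x)
  ny <- length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)])
  ties <- table(r)
  mu <- nx * (ny + nx + 1) / 2
  sigma2 <- nx * ny / 12 * ((nx + ny + 1) - sum(ties^3 - ties) / ((nx + ny) * (nx + ny - 1)))
  z <- if (sigma2 > 0) (w - mu) / sqrt(sigma2) else 0
  if (nx + ny <= exact_limit) {
    p <- subset_sum_tail_p(as.integer(round(2 * r)), nx, 2 * w)
    method <- "exact"
  } else {
    p <- if (sigma2 > 0) 2 * stats::pnorm(-abs(z)) else 1
    method <- "normal"
  }
  list(rank_sum = w, statistic = z, p = min(1, p), method = method, n_x = nx, n_y = ny)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped; absolute differences are midranked. The
#' reported `statistic` is W, the sum of ranks carrying the less frequent
#' difference sign (ties between sign frequencies report the positive-sign
#' rank sum). The two-sided p-value is the exact tie-aware sign-flip
#' probability when at most `exact_limit` non-zero differences remain,
#' else the tie-corrected normal approximation. With all differences zero
#' the test is degenerate and `p = 1`.
#'
#' @param x,y Equal-length paired samples.
#' @param exact_limit Largest number of non-zero differences for which the
#'   exact distribution is used (default 40).
#' @return List: `statistic` (W), `rank_sum_pos`, `rank_sum_neg`, `p`,
#'   `method`, `n` (non-zero differences).
#' @export
signed_rank_test <- function(x, y, exact_limit = 40) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[!is.na(d) & d != 0]
  if (!length(d)) {
    return(list(
      statistic = 0, rank_sum_pos = 0, rank_sum_neg = 0,
      p = 1, method = "degenerate", n = 0L
    ))
  }
  r <- rank(abs(d))
  pos <- sum(r[d > 0])
  neg <- sum(r[d < 0])
  w <- if (sum(d < 0) < sum(d > 0)) neg else pos
  n <- length(d)
  if (n <= exact_limit) {
    p <- sign_sum_tail_p(as.integer(round(2 * r)), 2 * pos)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    p <- if (sigma2 > 0) 2 * stats::pnorm(-abs(pos - mu) / sqrt(sigma2)) else 1
    method <- "normal"
  }
  list(
    statistic = w, rank_sum_pos = pos, rank_sum_neg = neg,
    p = min(1, p), method = method, n = n
  )
}

#' Levene's test of variance homogeneity (median-centred)
#'
#' One-way ANOVA on absolute deviations from the group centre; the default
#' centre is the median (the Brown-Forsythe variant, robust to
#' non-normality), configurable to the mean.
#'
#' @param x,y Numeric samples (each of size >= 2).
#' @param center `"median"` or `"mean"`.
#' @return List: `statistic` (F), `p`, `df1`, `df2`. Degenerate input
#'   (zero spread everywhere) gives statistic 0 and `p = 1`.
#' @export
levene_test <- function(x, y, center = c("median", "mean")) {
  center <- match.arg(center)
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  stopifnot(length(x) >= 2, length(y) >= 2)
  vals <- c(x, y)
  grp <- factor(rep(c("x", "y"), c(length(x), length(y))))
  centre_fun <- if (center == "median") stats::median else mean
  dev <- abs(vals - stats::ave(vals, grp, FUN = centre_fun))
  if (all(dev == 0)) {
    return(list(statistic = 0, p = 1, df1 = 1L, df2 = length(vals) - 2L))
  }
  lt <- suppressWarnings(car::leveneTest(vals, grp, center = centre_fun))
  list(
    statistic = lt[["F value"]][[1]], p = lt[["Pr(>F)"]][[1]],
    df1 = lt[["Df"]][[1]], df2 = lt[["Df"]][[2]]
  )
}

#' Full group-level comparison of an atypicality analysis
#'
#' Runs the chi-square test on typicality counts and the rank-sum and
#' Levene tests on per-player mean atypicality, patients versus controls.
#'
#' @param matrix An `atypicality_matrix`.
#' @param grain Counting grain for [typicality_counts()].
#' @return A list: `counts`, `chisq`, `rank_sum`, `levene`,
#'   `prevalence` (per group, proportion of players atypical on >= 1
#'   metric), `options`.
#' @export
group_stats <- function(matrix, grain = c("boolean", "cell")) {
  grain <- match.arg(grain)
  counts <- typicality_counts(matrix, grain)
  ma <- mean_atypicality(matrix)
  pa <- ma$mean_atypicality[ma$group == "patient"]
  co <- ma$mean_atypicality[ma$group == "control"]
  prevalence <- ma |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_atypical = sum(.data$n_flagged >= 1, na.rm = TRUE),
      pct_atypical = 100 * .data$n_atypical / .data$n,
      .groups = "drop"
    )
  list(
    counts = counts,
    chisq = chisq_2x2(counts),
    rank_sum = rank_sum_test(pa[!is.na(pa)], co[!is.na(co)]),
    levene = levene_test(pa[!is.na(pa)], co[!is.na(co)]),
    prevalence = prevalence,
    options = list(grain = grain, levene_center = "median", chisq_correct = FALSE)
  )
}
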