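# Exact nonparametric statistics for the crossover design.
#
# Within-animal contrasts (e.g. drug minus vehicle deltas) are tested with
# the exact Wilcoxon matched-pairs signed-rank test; between-group
# contrasts with the exact Mann-Whitney test. Exact p-values come from the
# full null distribution, computed by integer dynamic programming over
# doubled midranks -- arithmetically identical to enumerating all 2^n sign
# assignments (signed rank) or all C(N, n_a) group labelings (Mann-Whitney),
# including tied data. Two-sided p = min(1, 2 * min(lower, upper tail)).

# counts of the signed-rank statistic distribution on the doubled scale:
# f[s + 1] = number of sign assignments with 2 * W = s
signed_rank_counts <- function(ranks2) {
  s_max <- sum(ranks2)
  f <- numeric(s_max + 1)
  f[1] <- 1
  for (r in ranks2) {
    g <- f
    g[(r + 1):(s_max + 1)] <- g[(r + 1):(s_max + 1)] + f[1:(s_max + 1 - r)]
    f <- g
  }
  f
}

#' Exact Wilcoxon matched-pairs signed-rank test
#'
#' Zero deltas are dropped; |deltas| are midranked. For n <= `exact_max`
#' the two-sided p-value is exact over all `2^n` sign assignments (via the
#' equivalent rank-sum distribution); for larger n a normal approximation
#' with continuity and tie correction is used and flagged.
#'
#' @param deltas numeric vector of within-subject differences.
#' @param exact_max largest n for the exact computation.
#' @return list: `statistic` (W = sum of positive ranks), `p_value`
#'   (two-sided), `n` (after dropping zeros), `exact`, `degenerate`.
#' @export
wilcoxon_signed_rank_exact <- function(deltas, exact_max = 25) {
  stopifnot(is.numeric(deltas), length(deltas) >= 1)
  d <- deltas[deltas != 0]
  n <- length(d)
  if (n == 0) {
    return(list(statistic = 0, p_value = 1, n = 0, exact = TRUE,
                degenerate = TRUE))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_max) {
    r2 <- as.integer(round(2 * r))
    f <- signed_rank_counts(r2)
    total <- 2^n
    w2 <- round(2 * w)
    p_lo <- sum(f[seq_len(w2 + 1)]) / total
    p_hi <- sum(f[(w2 + 1):length(f)]) / total
    p <- min(1, 2 * min(p_lo, p_hi))
    list(statistic = w, p_value = p, p_one_sided = min(p_lo, p_hi),
         n = n, exact = TRUE, degenerate = FALSE)
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    list(statistic = w, p_value = min(1, 2 * stats::pnorm(-abs(z))),
         n = n, exact = FALSE, degenerate = FALSE)
  }
}

# counts over (subset size, doubled rank sum) for Mann-Whitney
subset_sum_counts <- function(ranks2, n_a) {
  s_max <- sum(ranks2)
  g <- matrix(0, nrow = n_a + 1, ncol = s_max + 1)
  g[1, 1] <- 1
  for (r in ranks2) {
    for (k in n_a:1) {
      nz <- which(g[k, ] > 0)
      if (length(nz)) {
        g[k + 1, nz + r] <- g[k + 1, nz + r] + g[k, nz]
      }
    }
  }
  g[n_a + 1, ]
}

#' Exact Mann-Whitney test
#'
#' For `n_a + n_b <=` `exact_max` the two-sided p-value is exact over all
#' `C(n_a + n_b, n_a)` labelings of the pooled midranks; for larger samples
#' a normal approximation with continuity and tie correction is used and
#' flagged.
#'
#' @param group_a,group_b numeric vectors (both nonempty).
#' @param exact_max largest pooled n for the exact computation.
#' @return list: `statistic` (U of group A), `p_value` (two-sided), `n_a`,
#'   `n_b`, `exact`.
#' @export
mann_whitney_exact <- function(group_a, group_b, exact_max = 20) {
  stopifnot(length(group_a) >= 1, length(group_b) >= 1)
  n_a <- length(group_a); n_b <- length(group_b)
  pooled <- c(group_a, group_b)
  r <- rank(pooled)
  w_a <- sum(r[seq_len(n_a)])
  u <- w_a - n_a * (n_a + 1) / 2
  if (n_a + n_b <= exact_max) {
    r2 <- as.integer(round(2 * r))
    f <- subset_sum_counts(r2, n_a)
    total <- choose(n_a + n_b, n_a)
    w2 <- round(2 * w_a)
    p_lo <- sum(f[seq_len(w2 + 1)]) / total
    p_hi <- sum(f[(w2 + 1):length(f)]) / total
    p <- min(1, 2 * min(p_lo, p_hi))
    list(statistic = u, p_value = p, n_a = n_a, n_b = n_b, exact = TRUE)
  } else {
    mu <- n_a * n_b / 2
    nn <- n_a + n_b
    ties <- table(r)
    sigma2 <- n_a * n_b / 12 *
      (nn + 1 - sum(ties^3 - ties) / (nn * (nn - 1)))
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    list(statistic = u, p_value = min(1, 2 * stats::pnorm(-abs(z))),
         n_a = n_a, n_b = n_b, exact = FALSE)
  }
}

#' Tukey boxplot summary
#'
#' Median, quartiles by linear interpolation (`stats::quantile` type 7 --
#' the convention is documented, not universal), whiskers at the most
#' extreme data within 1.5 IQR of the quartiles, and the outliers beyond.
#'
#' @param values numeric vector, n >= 1.
#' @return list: `median`, `q1`, `q3`, `iqr`, `whisker_lo`, `whisker_hi`,
#'   `outliers`, `n`.
#' @export
boxplot_summary <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 1)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values[values >= lo_fence & values <= hi_fence]
  list(median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
       whisker_lo = min(inside), whisker_hi = max(inside),
       outliers = sort(values[values < lo_fence | values > hi_fence]),
       n = length(values))
}

#' Paired crossover deltas
#'
#' Builds the per-subject `condition2 - condition1` contrast table for a
#' two-arm crossover; each subject must appear exactly once per condition.
#'
#' @param subject,condition,value aligned vectors.
#' @param order `c(reference, treatment)` condition labels; delta =
#'   treatment - reference.
#' @return data frame: `subject`, the two condition columns, `delta`.
#' @export
paired_deltas <- function(subject, condition, value, order = NULL) {
  stopifnot(length(subject) == length(condition),
            length(condition) == length(value))
  conds <- if (is.null(order)) sort(unique(condition)) else order
  if (length(conds) != 2) stop("exactly two conditions required")
  tab <- table(subject, condition)
  if (any(tab[, conds] != 1)) {
    stop("each subject must appear exactly once per condition")
  }
  subj <- sort(unique(subject))
  v1 <- value[match(paste(subj, conds[1]), paste(subject, condition))]
  v2 <- value[match(paste(subj, conds[2]), paste(subject, condition))]
  out <- data.frame(subject = subj, v1 = v1, v2 = v2, delta = v2 - v1)
  names(out)[2:3] <- conds
  out
}
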