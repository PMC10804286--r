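# shared fixtures: all inputs are generated in code at test time

# pure sinusoidal "flow" at frequency f_hz (breaths at f_hz per second)
make_sine_flow <- function(f_hz = 2.5, duration = 60, fs = 1000, amp = 1) {
  t <- (0:(duration * fs - 1)) / fs
  amp * sin(2 * pi * f_hz * t)
}

# event-free quiet generator configuration (no apneas, no extra desats)
quiet_config <- function(seed = 1, duration = 120, ...) {
  synth_config(seed = seed, duration = duration,
               apnea = list(rate = c(W = 0, NREM = 0, REM = 0)), ...)
}

# REM-dominated hypnogram settings (REM self-loop after a short lead-in)
rem_heavy <- function(rem_bout = 500) {
  list(transition = list(W = c(REM = 1), NREM = c(REM = 1), REM = c(REM = 1)),
       bout_mean = c(W = 30, NREM = 40, REM = rem_bout))
}

# match analysis breaths to generator truth rows by onset time
match_truth <- function(breaths, truth_table, tol = 2e-3) {
  m <- vapply(breaths$t_start, function(t0) {
    d <- abs(truth_table$t_start - t0)
    if (min(d) <= tol) which.min(d) else NA_integer_
  }, 0L)
  m
}

# brute-force exact Wilcoxon signed-rank two-sided p by enumerating all
# 2^n sign assignments (independent oracle for the DP implementation)
brute_wilcoxon <- function(deltas) {
  d <- deltas[deltas != 0]
  n <- length(d)
  if (n == 0) return(list(statistic = 0, p_value = 1))
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% r)
  p_lo <- mean(w_all <= w_obs + 1e-9)
  p_hi <- mean(w_all >= w_obs - 1e-9)
  list(statistic = w_obs, p_value = min(1, 2 * min(p_lo, p_hi)))
}

# brute-force exact Mann-Whitney two-sided p over all C(N, n_a) labelings
brute_mann_whitney <- function(a, b) {
  n_a <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n_a)])
  u_obs <- w_obs - n_a * (n_a + 1) / 2
  combos <- utils::combn(length(pooled), n_a)
  w_all <- apply(combos, 2, function(ix) sum(r[ix]))
  p_lo <- mean(w_all <= w_obs + 1e-9)
  p_hi <- mean(w_all >= w_obs - 1e-9)
  list(statistic = u_obs, p_value = min(1, 2 * min(p_lo, p_hi)))
}
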