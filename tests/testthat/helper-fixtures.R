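## Shared fixtures and scaled-down sampler settings used across test files.
## Sampling tests use fewer tuning steps and draws than the analysis defaults
## so the whole suite stays fast; convergence is still checked everywhere.

quick_config <- function(seed = 1L, tune = 800, draws = 1500) {
  sampler_config(chains = 2, tune = tune, draws = draws, seed = seed)
}

## deterministic 5-point dataset used by hand-computed likelihood oracles
tiny_dataset <- function() {
  allometry_dataset(N = c(10, 1e3, 1e6, 1e9, 1e12),
                    K = c(2, 7, 30, 80, 300))
}

empty_dataset <- function() allometry_dataset(numeric(0), numeric(0))

dr_const_spec <- function() model_spec("diminishing_returns", "constant")
dpl_const_spec <- function() model_spec("double_power_law", "constant")

## batch-means Monte Carlo standard error of a statistic of MCMC draws:
## batches are formed within each chain so autocorrelation is respected
mc_se <- function(draws_mat, stat, batches_per_chain = 10) {
  v <- numeric(0)
  idx <- cut(seq_len(ncol(draws_mat)), batches_per_chain, labels = FALSE)
  for (ch in seq_len(nrow(draws_mat))) {
    v <- c(v, tapply(draws_mat[ch, ], idx, stat))
  }
  stats::sd(v) / sqrt(length(v))
}

## brute-force smallest-window HDI used as the oracle for hdi()
hdi_scan_oracle <- function(x, prob) {
  xs <- sort(x)
  S <- length(xs)
  m <- ceiling(prob * S)
  if (m >= S) return(c(xs[1], xs[S]))
  best <- c(Inf, NA, NA)
  for (i in seq_len(S - m + 1)) {
    w <- xs[i + m - 1] - xs[i]
    if (w < best[1]) best <- c(w, xs[i], xs[i + m - 1])
  }
  best[2:3]
}
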