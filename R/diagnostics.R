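## Convergence diagnostics: split-R-hat and autocorrelation-based effective
## sample size, following the standard formulation (split chains, FFT
## autocovariance, Geyer initial-positive-sequence truncation).

autocov_fft <- function(x) {
  n <- length(x)
  xc <- x - mean(x)
  m <- stats::nextn(2L * n)
  f <- stats::fft(c(xc, rep(0, m - n)))
  a <- Re(stats::fft(f * Conj(f), inverse = TRUE)) / m
  a[seq_len(n)] / n
}

## sims: iterations x chains matrix of one parameter's draws (already or not
## yet split; this function splits each chain in half first).
split_diagnostics <- function(sims) {
  L0 <- nrow(sims)
  half <- floor(L0 / 2)
  sims <- cbind(sims[seq_len(half), , drop = FALSE],
                sims[(L0 - half + 1):L0, , drop = FALSE])
  L <- nrow(sims)
  m <- ncol(sims)
  if (L < 4) return(list(rhat = NA_real_, ess = NA_real_))
  if (stats::sd(as.vector(sims)) == 0) return(list(rhat = 1, ess = L * m))
  chain_means <- colMeans(sims)
  chain_vars <- apply(sims, 2, stats::var)
  W <- mean(chain_vars)
  B_over_L <- stats::var(chain_means)
  var_plus <- (L - 1) / L * W + B_over_L
  rhat <- sqrt(var_plus / W)
  acov <- vapply(seq_len(m), function(j) autocov_fft(sims[, j]), numeric(L))
  mean_acov <- rowMeans(acov) * L / (L - 1)
  rho <- 1 - (W - mean_acov) / var_plus
  ## Geyer: sum consecutive pairs while positive, enforce monotone decrease
  max_t <- L - 2
  tau <- 0
  prev_pair <- Inf
  t <- 1L
  pair_sum <- rho[1] + rho[2]           # lag 0 + lag 1
  while (t < max_t && pair_sum > 0) {
    pair_sum <- min(pair_sum, prev_pair)
    tau <- tau + pair_sum
    prev_pair <- pair_sum
    t <- t + 2L
    if (t + 1 > L) break
    pair_sum <- rho[t] + rho[t + 1]
  }
  tau <- max(2 * tau - 1, 1 / (L * m))  # integrated autocorrelation time
  ess <- min(L * m / tau, L * m)
  list(rhat = rhat, ess = ess)
}
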