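## Hand-built posterior objects let the band computations be checked against
## brute-force recomputation without running the sampler.
toy_samples <- function(draws_mat, spec) {
  n_draw <- nrow(draws_mat)
  arr <- array(NA_real_, dim = c(2, ceiling(n_draw / 2), ncol(draws_mat)),
               dimnames = list(NULL, NULL, colnames(draws_mat)))
  half <- ceiling(n_draw / 2)
  for (j in seq_len(ncol(draws_mat))) {
    arr[1, , j] <- draws_mat[seq_len(half), j]
    arr[2, , j] <- draws_mat[(n_draw - half + 1):n_draw, j]
  }
  structure(list(draws = arr, lp = matrix(0, 2, half),
                 rhat = stats::setNames(rep(1, ncol(draws_mat)), colnames(draws_mat)),
                 ess = stats::setNames(rep(n_draw, ncol(draws_mat)), colnames(draws_mat)),
                 divergences = 0L, converged = TRUE,
                 spec = spec, config = NULL, n_obs = 0, fingerprint = ""),
            class = "posterior_samples")
}

test_that("posterior_curve matches a brute-force recomputation on a toy posterior", {
  set.seed(14)
  spec <- dr_const_spec()
  th <- cbind(A = runif(200, 0.2, 0.8), B = runif(200, 0.8, 1.4),
              Sigma = runif(200, 0.2, 0.5))
  samples <- toy_samples(th, spec)
  grid <- seq(1, 12, length.out = 15)
  cb <- posterior_curve(samples, grid = grid, seed = 77)

  # brute force, same predictive stream
  th_flat <- cellallometry:::flatten_draws(samples)
  set.seed(77)
  for (g in seq_along(grid)) {
    mu <- log10(th_flat[, "A"] + th_flat[, "B"] * grid[g])
    expect_equal(cb$mean[g], mean(mu))
    expect_equal(unname(hdi(mu, 0.95)), c(cb$hdi_lo[g], cb$hdi_hi[g]))
    ks <- rnorm(length(mu), mu, th_flat[, "Sigma"])
    expect_equal(unname(hdi(ks, 0.95)), c(cb$ppd_lo[g], cb$ppd_hi[g]))
  }
})

test_that("predictive band strictly contains the curve band when sigma > 0", {
  set.seed(15)
  th <- cbind(A = runif(400, 0.2, 0.8), B = runif(400, 0.8, 1.4),
              Sigma = runif(400, 0.3, 0.5))
  cb <- posterior_curve(toy_samples(th, dr_const_spec()),
                        grid = seq(2, 12, length.out = 10), seed = 5)
  expect_true(all(cb$ppd_lo < cb$hdi_lo))
  expect_true(all(cb$ppd_hi > cb$hdi_hi))
})

test_that("a degenerate one-point posterior gives zero-width curve bands", {
  th <- cbind(A = c(0.5, 0.5), B = c(1, 1), Sigma = c(0.3, 0.3))
  cb <- posterior_curve(toy_samples(th, dr_const_spec()),
                        grid = c(2, 6, 10), seed = 1)
  expect_equal(cb$mean, log10(0.5 + c(2, 6, 10)))
  expect_equal(cb$hdi_lo, cb$hdi_hi)
  expect_equal(cb$hdi_lo, cb$mean)
})

test_that("domain-violating draws are excluded and counted", {
  # half the draws undefined at n = 1 (A + B*n < 0)
  th <- cbind(A = c(rep(-2, 100), rep(0.5, 100)), B = rep(1, 200),
              Sigma = rep(0.3, 200))
  expect_warning(
    cb <- posterior_curve(toy_samples(th, dr_const_spec()), grid = c(1, 10), seed = 2),
    "excluded")
  expect_equal(cb$n_excluded, c(100, 0))
  expect_equal(cb$mean[1], log10(0.5 + 1))
})

test_that("summaries pool chains exactly", {
  # constant chains at one value: mean v, zero-width HDI
  th0 <- cbind(A = rep(2.5, 10), B = rep(1, 10), Sigma = rep(0.3, 10))
  s0 <- summarize_posterior(toy_samples(th0, dr_const_spec()))
  expect_equal(s0$mean[1], 2.5)
  expect_equal(s0$hdi_lo[1], 2.5)
  expect_equal(s0$hdi_hi[1], 2.5)

  # two chains with a known pooled mean
  th <- cbind(A = c(rep(1, 5), rep(3, 5)), B = rep(1, 10), Sigma = rep(0.3, 10))
  s <- summarize_posterior(toy_samples(th, dr_const_spec()))
  expect_equal(s$mean[s$parameter == "A"], 2)
})

test_that("summary JSON mirrors the parameter table", {
  th <- cbind(A = rnorm(50, 0.5, 0.1), B = rnorm(50, 1, 0.1),
              Sigma = runif(50, 0.2, 0.4))
  samples <- toy_samples(th, dr_const_spec())
  f <- withr::local_tempfile(fileext = ".json")
  write_summary_json(samples, f)
  doc <- jsonlite::read_json(f, simplifyVector = FALSE)
  expect_equal(doc$model, "dr_const")
  expect_equal(length(doc$parameters), 3)
  expect_equal(doc$parameters[[1]]$name, "A")
  s <- summarize_posterior(samples)
  expect_equal(doc$parameters[[1]]$mean, s$mean[1])
})

test_that("long-format sample export round-trips values", {
  th <- cbind(A = rnorm(20), B = rnorm(20), Sigma = runif(20, 0.1, 1))
  samples <- toy_samples(th, dr_const_spec())
  f <- withr::local_tempfile(fileext = ".csv")
  write_samples_csv(samples, f)
  long <- read.csv(f)
  expect_equal(nrow(long), 2 * 10 * 3)
  expect_setequal(unique(long$parameter), c("A", "B", "Sigma"))
  back <- long$value[long$parameter == "A" & long$chain == 1]
  expect_equal(back, samples$draws[1, , "A"])
})
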