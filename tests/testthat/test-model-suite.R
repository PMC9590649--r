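test_that("model_spec defines the four models with their parameters", {
  expect_equal(model_spec("double_power_law", "constant")$par_names,
               c("k0", "s_small", "n_bp", "s_large", "Sigma"))
  expect_equal(model_spec("diminishing_returns", "variable")$par_names,
               c("A", "B", "Sigma0", "s_Sigma"))
  expect_equal(model_spec_by_name("dr_const")$name, "dr_const")
  expect_error(model_spec_by_name("nope"), "unknown model")
})

test_that("double power law mean is continuous and collapses to one line", {
  set.seed(3)
  for (i in 1:1000) {
    p <- c(k0 = runif(1, -0.5, 0.5), s_small = rnorm(1, 0, 2),
           n_bp = runif(1, 1, 10), s_large = rnorm(1, 0, 2))
    lo <- p[["k0"]] + p[["s_small"]] * p[["n_bp"]]
    hi <- mean_double_power_law(p[["n_bp"]], p)
    expect_equal(hi, lo, tolerance = 1e-12)
  }
  p <- c(k0 = 0.1, s_small = 0.3, n_bp = 5, s_large = 0.3)
  n <- seq(0, 12, by = 0.5)
  expect_equal(mean_double_power_law(n, p), 0.1 + 0.3 * n)
  # arithmetic with published-style posterior means: both branches at n = n_bp
  p2 <- c(k0 = -0.20, s_small = 0.21, n_bp = 4.82, s_large = 0.07)
  expect_equal(mean_double_power_law(4.82, p2), -0.20 + 0.21 * 4.82)
})

test_that("diminishing-returns mean follows log10(A + B n) with NaN outside domain", {
  expect_equal(mean_diminishing_returns(2, c(A = -1, B = 1)), 0)  # A + Bn = 1
  expect_equal(mean_diminishing_returns(2, c(A = 0, B = 1)), log10(2))
  expect_equal(mean_diminishing_returns(4, c(A = -0.29, B = 1.29)),
               log10(-0.29 + 1.29 * 4))
  expect_true(is.nan(mean_diminishing_returns(0.1, c(A = -1, B = 1))))
})

test_that("diminishing-returns mean equals the fitness model capacity in log10", {
  p <- fitness_params(a = 3, b = 2.2, c = 1.4, gamma = 1.1, delta = 0.4)
  cf <- closed_form_coefficients(p)
  n <- seq(1, 12, by = 0.25)
  expect_equal(mean_diminishing_returns(n, c(A = cf$A, B = cf$B)),
               log10(capacity(10^n, cf)))
})

test_that("sd_function handles constant and linearly varying noise", {
  expect_equal(sd_function(c(0, 3, 14), c(Sigma = 0.33)), rep(0.33, 3))
  expect_equal(sd_function(0, c(Sigma0 = 0.12, s_Sigma = 0.03)), 0.12)
  expect_equal(sd_function(10, c(Sigma0 = 0.12, s_Sigma = 0.03)), 0.42)
  expect_error(sd_function(1, c(bogus = 1)), "noise")
})

test_that("pointwise log likelihood matches per-point normal arithmetic", {
  spec <- dr_const_spec()
  # a single point exactly on the curve with sigma = 1
  d1 <- allometry_dataset(N = 100, K = 10^mean_diminishing_returns(2, c(A = 0.5, B = 1)))
  ll1 <- pointwise_log_likelihood(d1, spec, c(A = 0.5, B = 1, Sigma = 1))
  expect_equal(ll1, -0.5 * log(2 * pi))

  # additivity: a duplicated observation contributes twice
  d2 <- allometry_dataset(N = c(100, 100), K = rep(d1$K, 2))
  ll2 <- pointwise_log_likelihood(d2, spec, c(A = 0.5, B = 1, Sigma = 1))
  expect_equal(sum(ll2), 2 * sum(ll1))

  # 5-point dataset against an independent per-point oracle
  d5 <- tiny_dataset()
  pars <- c(A = -0.3, B = 1.3, Sigma = 0.4)
  ll <- pointwise_log_likelihood(d5, spec, pars)
  oracle <- vapply(seq_len(5), function(i) {
    mu <- log10(-0.3 + 1.3 * d5$n[i])
    -0.5 * log(2 * pi * 0.4^2) - (d5$k[i] - mu)^2 / (2 * 0.4^2)
  }, numeric(1))
  expect_equal(ll, oracle)
  expect_equal(sum(ll), sum(oracle))

  # domain violation encodes as -Inf, not an error
  ll_bad <- pointwise_log_likelihood(d5, spec, c(A = -10, B = 1, Sigma = 0.4))
  expect_true(any(ll_bad == -Inf))
  var_spec <- model_spec("diminishing_returns", "variable")
  ll_sd <- pointwise_log_likelihood(d5, var_spec,
                                    c(A = 0.5, B = 1, Sigma0 = 0.1, s_Sigma = -0.2))
  expect_true(any(ll_sd == -Inf))
})

test_that("likelihood is permutation-equivariant", {
  d <- tiny_dataset()
  spec <- dpl_const_spec()
  pars <- c(k0 = -0.2, s_small = 0.21, n_bp = 4.82, s_large = 0.07, Sigma = 0.32)
  ll <- pointwise_log_likelihood(d, spec, pars)
  perm <- c(3, 1, 5, 2, 4)
  dperm <- allometry_dataset(d$N[perm], d$K[perm])
  expect_equal(pointwise_log_likelihood(dperm, spec, pars), ll[perm])
  expect_equal(sum(pointwise_log_likelihood(dperm, spec, pars)), sum(ll))
})

test_that("log prior matches closed-form densities and support", {
  spec <- dpl_const_spec()
  inside <- c(k0 = 0.1, s_small = 0, n_bp = 5, s_large = 0, Sigma = 10)
  outside <- inside; outside[["k0"]] <- 0.7
  expect_equal(log_prior(spec, outside), -Inf)
  expect_equal(log_prior(spec, replace(inside, "Sigma", -1)), -Inf)

  # per-term arithmetic oracle at the prior modes (Sigma at its scale point):
  # Uniform(-0.5, 0.5) -> log 1; Normal(0, 20) at 0 -> -log(20 sqrt(2 pi));
  # Normal(5, 2) at 5 -> -log(2 sqrt(2 pi));
  # HalfCauchy(10) at 10 -> log 2 + log(1 / (2 pi 10)) = -log(10 pi)
  oracle <- log(1) +
    2 * (-log(20 * sqrt(2 * pi))) +
    (-log(2 * sqrt(2 * pi))) +
    (-log(10 * pi))
  expect_equal(log_prior(spec, inside), oracle)

  # half-normal carries the factor-2 normalization
  spec_v <- model_spec("diminishing_returns", "variable")
  lp <- log_prior(spec_v, c(A = 0, B = 0, Sigma0 = 0.4, s_Sigma = 0.1))
  oracle_v <- 2 * (-log(20 * sqrt(2 * pi))) +
    (log(2) + dnorm(0.4, 0, 1, log = TRUE)) +
    (log(2) + dnorm(0.1, 0, 1, log = TRUE))
  expect_equal(lp, oracle_v)
})

test_that("each univariate prior integrates to one", {
  pld <- cellallometry:::prior_log_density
  specs <- list(model_spec("double_power_law", "variable"),
                model_spec("diminishing_returns", "constant"))
  seen <- character()
  for (spec in specs) {
    for (nm in spec$par_names) {
      if (nm %in% seen) next
      seen <- c(seen, nm)
      pr <- spec$priors[[nm]]
      lo <- if (pr$dist %in% c("halfcauchy", "halfnormal")) 0 else
        if (pr$dist == "uniform") pr$lo else -Inf
      hi <- if (pr$dist == "uniform") pr$hi else Inf
      val <- stats::integrate(function(x) exp(pld(pr, x)), lo, hi,
                              rel.tol = 1e-9)$value
      expect_equal(val, 1, tolerance = 1e-6)
    }
  }
})

test_that("log posterior is prior plus likelihood with -Inf propagation", {
  d <- tiny_dataset()
  spec <- dr_const_spec()
  set.seed(9)
  for (i in 1:20) {
    pars <- c(A = runif(1, 0.1, 2), B = runif(1, 0.5, 2), Sigma = runif(1, 0.1, 1))
    expect_equal(log_posterior(d, spec, pars),
                 log_prior(spec, pars) + sum(pointwise_log_likelihood(d, spec, pars)))
  }
  expect_equal(log_posterior(d, spec, c(A = 1, B = 1, Sigma = -2)), -Inf)
  # empty dataset: posterior reduces to the prior
  expect_equal(log_posterior(empty_dataset(), spec, c(A = 1, B = 1, Sigma = 0.3)),
               log_prior(spec, c(A = 1, B = 1, Sigma = 0.3)))
})

test_that("parameter points round-trip through flat JSON", {
  pars <- c(A = -0.29, B = 1.29, Sigma = 0.33)
  f <- withr::local_tempfile(fileext = ".json")
  params_to_json(pars, f)
  expect_equal(params_from_json(f), pars)
})
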