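test_that("fitness_params validates its invariants", {
  expect_error(fitness_params(a = -1, b = 2, c = 1, gamma = 1, delta = 0), "'a'")
  expect_error(fitness_params(a = 1, b = 1, c = 1, gamma = 1, delta = 0), "'b'")
  expect_error(fitness_params(a = 1, b = 0.5, c = 1, gamma = 1, delta = 0), "'b'")
  expect_error(fitness_params(a = 1, b = 2, c = 0, gamma = 1, delta = 0), "'c'")
  expect_warning(fitness_params(a = 1, b = 2, c = 1, gamma = 0, delta = 1),
                 "gamma <= delta")
  p <- fitness_params(a = 2, b = 1.5, c = 1, gamma = 1, delta = 0.75)
  expect_s3_class(p, "fitness_params")
})

test_that("delta_fitness matches hand arithmetic and splits into components", {
  # gamma = delta = 0 is the deliberately degenerate oracle case; the
  # capacity-growth warning is expected
  p0 <- suppressWarnings(fitness_params(a = 1, b = 2, c = 1, gamma = 0, delta = 0))
  # K = 0: benefit b^0 = 1 equals cost
  expect_equal(delta_fitness(5, 0, p0), 0)
  expect_equal(delta_fitness(123.4, 0, p0), 0)
  # exact dyadic value at N = 1, K = 10
  expect_equal(delta_fitness(1, 10, p0), 2^-10 - 1)
  expect_equal(delta_fitness(1, 10, p0), -1023 / 1024)

  # three factors computed separately as the oracle
  p <- fitness_params(a = 2, b = 1.5, c = 1, gamma = 1, delta = 0.75)
  benefit <- 2 * (1e4^1) * (1.5^-3)
  cost <- 1 * (1e4^0.75)
  expect_equal(delta_fitness(1e4, 3, p), benefit - cost)
  expect_equal(delta_fitness(1e4, 3, p, component = "benefit"), benefit)
  expect_equal(delta_fitness(1e4, 3, p, component = "cost"), cost)

  expect_error(delta_fitness(-1, 2, p), "'N'")
  expect_error(delta_fitness(Inf, 2, p), "'N'")
  expect_error(delta_fitness(10, -1, p), "'K'")
})

test_that("delta_fitness strictly decreases in K for b > 1", {
  params <- list(fitness_params(1, 2, 1, 0.5, 0.2),
                 fitness_params(3, 1.2, 0.5, 1, 0),
                 fitness_params(0.1, 10, 2, 2, 1.5))
  # grid kept moderate so the geometric benefit term stays representable
  # next to the cost term (it underflows to a constant in double precision
  # for very large K, where the mathematical decrease is below 1 ulp)
  for (p in params) {
    for (N in 10^c(0.5, 2, 4, 6)) {
      df <- delta_fitness(N, seq(0, 12, by = 0.5), p)
      expect_true(all(diff(df) < 0))
    }
  }
})

test_that("closed-form coefficients reproduce an independent root-find", {
  # trivial anchors
  expect_equal(closed_form_coefficients(fitness_params(2, 3, 2, 1, 0))$A, 0)
  expect_equal(closed_form_coefficients(fitness_params(1, 10, 3, 2, 1))$B, 1)

  p <- fitness_params(a = 3, b = 1.7, c = 2, gamma = 0.9, delta = 0.4)
  # oracle: solve delta_fitness(N, K) = 0 for K at two values of N by
  # numeric root-finding, then recover intercept and slope
  root_K <- function(N) {
    stats::uniroot(function(K) delta_fitness(N, K, p),
                   interval = c(0, 1e4), tol = 1e-12)$root
  }
  K1 <- root_K(1e2); K2 <- root_K(1e8)
  B_oracle <- (K2 - K1) / (8 - 2)
  A_oracle <- K1 - B_oracle * 2
  cf <- closed_form_coefficients(p)
  expect_equal(cf$A, A_oracle, tolerance = 1e-8)
  expect_equal(cf$B, B_oracle, tolerance = 1e-8)
})

test_that("capacity evaluates A + B log10 N", {
  expect_equal(capacity(100, list(A = 0, B = 1)), 2)
  expect_equal(capacity(1, list(A = -3.7, B = 42)), -3.7)
  # Table-style posterior means, direct arithmetic
  expect_equal(capacity(10^4.82, list(A = -0.29, B = 1.29)), -0.29 + 1.29 * 4.82)
  expect_error(capacity(0, list(A = 0, B = 1)), "'N'")
})

test_that("zero-crossing identity: delta_fitness vanishes at capacity", {
  set.seed(11)
  for (i in 1:50) {
    p <- fitness_params(a = runif(1, 0.1, 5), b = runif(1, 1.1, 8),
                        c = runif(1, 0.1, 5),
                        gamma = runif(1, 0.6, 2), delta = runif(1, 0, 0.5))
    cf <- closed_form_coefficients(p)
    for (N in 10^runif(4, 0.5, 12)) {
      K_star <- capacity(N, cf)
      if (K_star < 0) next
      df <- delta_fitness(N, K_star, p)
      expect_lt(abs(df), 1e-9 * p$c * N^p$delta)
    }
  }
})

test_that("accumulation simulator matches brute-force iteration", {
  # first event already rejected -> stays at the single ancestral type
  p_neg <- suppressWarnings(fitness_params(a = 1, b = 100, c = 1, gamma = 0, delta = 0))
  expect_equal(as.integer(simulate_accumulation(50, p_neg)), 1L)

  # a = c = 1, gamma = 1, delta = 0, b = 10 at N = 1000:
  # delta_f at K = 1, 2, 3 is 99, 9, 0 (accepted, boundary inclusive);
  # at K = 4 it is negative
  p <- fitness_params(a = 1, b = 10, c = 1, gamma = 1, delta = 0)
  expect_equal(delta_fitness(1000, 1:3, p), c(99, 9, 0))
  expect_lt(delta_fitness(1000, 4, p), 0)
  expect_equal(as.integer(simulate_accumulation(1000, p)), 4L)

  # cap flags runaway accumulation
  p_free <- fitness_params(a = 10, b = 1.0000001, c = 1, gamma = 1, delta = 0)
  expect_warning(res <- simulate_accumulation(10, p_free, k_max = 50), "cap")
  expect_true(attr(res, "capped"))
})

test_that("simulation agrees with the closed form across a parameter sweep", {
  # A = 0, B = 1 family: capacity is exactly log10 N
  p_unit <- fitness_params(a = 1, b = 10, c = 1, gamma = 1, delta = 0)
  for (e in 1:12) {
    K_sim <- as.integer(simulate_accumulation(10^e, p_unit))
    expect_lte(abs(K_sim - e), 1)
  }

  # >= 200 parameter/size combinations
  set.seed(42)
  combos <- 0L
  for (i in 1:60) {
    p <- fitness_params(a = runif(1, 0.2, 4), b = runif(1, 1.2, 6),
                        c = runif(1, 0.2, 4),
                        gamma = runif(1, 0.7, 1.6), delta = runif(1, 0, 0.4))
    cf <- closed_form_coefficients(p)
    for (N in 10^runif(4, 1, 12)) {
      K_sim <- as.integer(suppressWarnings(simulate_accumulation(N, p, k_max = 5000)))
      expect_lte(abs(K_sim - max(1, capacity(N, cf))), 1 + 1e-9)
      combos <- combos + 1L
    }
  }
  expect_gte(combos, 200L)
})

test_that("the capacity model is not a single power law", {
  # log10 K vs log10 N must be curved for B > 0, A != 0: nonzero second
  # difference of k(n) = log10(A + B n)
  n <- seq(1, 10, length.out = 25)
  for (AB in list(c(-0.29, 1.29), c(2, 0.7), c(-1, 1))) {
    kk <- log10(AB[1] + AB[2] * n)
    curv <- diff(diff(kk))
    expect_gt(max(abs(curv)), 1e-4)
  }
  # sanity: a true power law has zero curvature in log-log space
  expect_equal(max(abs(diff(diff(0.2 * n + 1)))), 0, tolerance = 1e-12)
})

test_that("fitness parameters round-trip through flat JSON", {
  p <- fitness_params(a = 2.5, b = 1.9, c = 0.7, gamma = 1.2, delta = 0.3)
  f <- withr::local_tempfile(fileext = ".json")
  fitness_params_to_json(p, f)
  q <- fitness_params_from_json(f)
  expect_equal(unclass(p), unclass(q))
  keys <- names(jsonlite::read_json(f))
  expect_setequal(keys, c("a", "b", "c", "gamma", "delta"))
})
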