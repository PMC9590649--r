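#' Pointwise log-likelihood matrix of a fitted model
#'
#' Evaluates the per-observation normal log density at every posterior draw.
#'
#' @param samples a [sample_posterior()] result.
#' @param dataset the [allometry_dataset()] the model was fit to.
#' @return Matrix (draws x observations) of natural-log densities.
#' @export
log_likelihood_matrix <- function(samples, dataset) {
  stopifnot(inherits(samples, "posterior_samples"),
            inherits(dataset, "allometry_dataset"))
  th <- flatten_draws(samples)
  spec <- samples$spec
  ll <- vapply(seq_len(nrow(dataset)), function(i) {
    mu <- model_mean_draws(spec, dataset$n[i], th)
    sigma <- model_sd_draws(spec, dataset$n[i], th)
    ok <- is.finite(mu) & sigma > 0
    out <- rep(-Inf, nrow(th))
    out[ok] <- stats::dnorm(dataset$k[i], mu[ok], sigma[ok], log = TRUE)
    out
  }, numeric(nrow(th)))
  ll
}

## Generalized Pareto fit to exceedances (Zhang & Stephens 2009, with the
## weakly informative prior regularization of the shape estimate).
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  prior_bs <- 3
  prior_k <- 10
  m_est <- 30L + floor(sqrt(n))
  jj <- seq_len(m_est)
  b <- 1 - sqrt(m_est / (jj - 0.5))
  b <- b / (prior_bs * x[max(1L, floor(n / 4 + 0.5))])
  b <- b + 1 / x[n]
  kk <- vapply(b, function(bj) mean(log1p(-bj * x)), numeric(1))
  L <- n * (log(-b / kk) - kk - 1)
  w <- vapply(jj, function(j) 1 / sum(exp(L - L[j])), numeric(1))
  w <- w / sum(w)
  b_post <- sum(b * w)
  k_raw <- mean(log1p(-b_post * x))
  sigma <- -k_raw / b_post            # scale from the unregularized shape
  k_post <- (n * k_raw + prior_k * 0.5) / (n + prior_k)
  list(k = k_post, sigma = sigma)
}

gpd_quantile <- function(p, k, sigma) {
  if (abs(k) < 1e-12) -sigma * log1p(-p) else sigma / k * ((1 - p)^(-k) - 1)
}

## Pareto-smoothed importance weights for one observation.
## lw: log raw importance ratios (length S). Returns normalized log weights
## and the Pareto shape diagnostic.
psis_smooth <- function(lw) {
  S <- length(lw)
  lw <- lw - max(lw)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  khat <- NA_real_
  if (M >= 5) {
    ord <- order(lw)
    tail_ids <- ord[(S - M + 1):S]
    cutoff <- lw[ord[S - M]]
    x_star <- exp(cutoff)
    exceed <- exp(lw[tail_ids]) - x_star
    if (length(unique(exceed)) >= 5 && max(exceed) > 0) {
      fit <- gpd_fit(exceed)
      khat <- fit$k
      if (is.finite(khat) && is.finite(fit$sigma) && fit$sigma > 0) {
        p <- (seq_len(M) - 0.5) / M
        qq <- vapply(p, gpd_quantile, numeric(1), k = khat, sigma = fit$sigma) + x_star
        smoothed <- log(qq)
        smoothed <- pmin(smoothed, 0)   # never exceed the raw maximum weight
        lw[tail_ids[order(lw[tail_ids])]] <- smoothed
      }
    }
  }
  # max_unnorm: largest smoothed weight relative to the raw maximum (<= 0 by
  # the truncation rule); kept for diagnostics and testing
  list(log_weights = lw - logsumexp(lw), khat = khat, max_unnorm = max(lw))
}

#' Leave-one-out expected log predictive density by PSIS
#'
#' Estimates the expected log predictive density (elpd) of leave-one-out
#' cross-validation from posterior draws, without refitting: for each
#' observation the importance ratios `1 / p(y_i | theta_s)` are stabilized by
#' fitting a generalized Pareto distribution to the largest
#' `ceiling(min(0.2 S, 3 sqrt(S)))` ratios and replacing them with expected
#' order statistics (truncated at the raw maximum), after which
#' `elpd_i = log( sum_s w_s p(y_i|theta_s) / sum_s w_s )`. All weight sums
#' use log-sum-exp. Natural-log units throughout.
#'
#' Observations with Pareto shape above 0.7 are flagged: their importance
#' weights are too heavy-tailed for a reliable estimate and an exact refit
#' ([exact_loo_refit()]) is advisable.
#'
#' @param loglik matrix (draws x observations) of pointwise log likelihoods,
#'   e.g. from [log_likelihood_matrix()]. Rows with non-finite values in
#'   every column are rejected.
#' @param model optional model name carried into the result.
#' @param fingerprint optional dataset fingerprint used by
#'   [compare_models()] to verify fits share a dataset.
#' @return An object of class `loo_result`: `elpd`, `se`, `pointwise`,
#'   `pareto_k`, `n_obs`, `lppd` (in-sample log pointwise predictive
#'   density), `model`, `fingerprint`.
#' @export
loo_elpd <- function(loglik, model = NULL, fingerprint = NULL) {
  if (!is.matrix(loglik) || nrow(loglik) < 2)
    stop_input("'loglik' must be a (draws x observations) matrix with >= 2 draws")
  if (any(!is.finite(loglik)))
    stop_input("'loglik' contains non-finite entries")
  n_obs <- ncol(loglik)
  pointwise <- numeric(n_obs)
  pareto_k <- numeric(n_obs)
  lppd <- numeric(n_obs)
  for (i in seq_len(n_obs)) {
    ll <- loglik[, i]
    sm <- psis_smooth(-ll)
    pointwise[i] <- logsumexp(sm$log_weights + ll)
    pareto_k[i] <- sm$khat
    lppd[i] <- logmeanexp(ll)
  }
  new_loo_result(pointwise, pareto_k, lppd, n_obs, model, fingerprint)
}

new_loo_result <- function(pointwise, pareto_k, lppd, n_obs, model, fingerprint) {
  structure(list(elpd = sum(pointwise),
                 se = sqrt(n_obs * stats::var(pointwise)),
                 pointwise = pointwise,
                 pareto_k = pareto_k,
                 lppd = sum(lppd),
                 n_obs = n_obs,
                 model = model,
                 fingerprint = fingerprint),
            class = "loo_result")
}

#' @export
print.loo_result <- function(x, ...) {
  cat(sprintf("LOO elpd: %.2f (se %.2f) over %d observations%s\n",
              x$elpd, x$se, x$n_obs,
              if (is.null(x$model)) "" else paste0(" [", x$model, "]")))
  nk <- sum(is.finite(x$pareto_k) & x$pareto_k > 0.7)
  if (nk > 0) cat(sprintf("  warning: %d observation(s) with Pareto k > 0.7\n", nk))
  invisible(x)
}

#' Exact leave-one-out cross-validation by refitting
#'
#' The brute-force oracle for [loo_elpd()]: the model is refit once per
#' observation with that observation held out, and
#' `elpd_i = log mean_s p(y_i | theta_s)` over the held-out fit's draws. For
#' a single-observation dataset the held-out fit is prior-only, so the
#' contribution is the prior-predictive log density.
#'
#' @param dataset an [allometry_dataset()] with at most 100 rows (guard
#'   against accidental large refit jobs).
#' @param spec a [model_spec()].
#' @param config a [sampler_config()]; refit `r` uses seed `seed + r`.
#' @return A `loo_result` (with `lppd` of the full-data fit omitted: the
#'   `lppd` field holds `NA`).
#' @export
exact_loo_refit <- function(dataset, spec, config = sampler_config()) {
  stopifnot(inherits(dataset, "allometry_dataset"))
  n <- nrow(dataset)
  if (n < 1) stop_input("dataset is empty")
  if (n > 100) stop_input("exact refit LOO is guarded to <= 100 observations")
  pointwise <- numeric(n)
  for (i in seq_len(n)) {
    cfg_i <- config
    cfg_i$seed <- (config$seed + i) %% .Machine$integer.max
    fit <- withCallingHandlers(
      sample_posterior(dataset[-i, , drop = FALSE], spec, cfg_i),
      warning = function(w) invokeRestart("muffleWarning"))
    if (!fit$converged)
      stop("exact LOO refit failed convergence with observation ", i,
           " held out (max R-hat ", sprintf("%.3f", max(fit$rhat)), ")",
           call. = FALSE)
    th <- flatten_draws(fit)
    mu <- model_mean_draws(spec, dataset$n[i], th)
    sigma <- model_sd_draws(spec, dataset$n[i], th)
    ok <- is.finite(mu) & sigma > 0
    ll <- rep(-Inf, nrow(th))
    ll[ok] <- stats::dnorm(dataset$k[i], mu[ok], sigma[ok], log = TRUE)
    pointwise[i] <- logmeanexp(ll)
  }
  new_loo_result(pointwise, rep(NA_real_, n), rep(NA_real_, n), n,
                 model = spec$name, fingerprint = dataset_fingerprint(dataset))
}

#' Rank models by leave-one-out elpd
#'
#' Sorts models by elpd (best first) and reports, for each model, the elpd
#' difference to the best model with the standard error of that difference
#' (computed pointwise). A difference within one standard error is labelled
#' `"indistinguishable"`. All fits must be on the same dataset, verified via
#' observation count and dataset fingerprint when available.
#'
#' @param fits a named list of `loo_result` objects (names are model labels;
#'   unnamed entries fall back to the result's own `model` field).
#' @return A `data.frame` of class `model_comparison` with columns `model`,
#'   `elpd`, `se`, `elpd_diff`, `se_diff`, `verdict`, `n_pareto_k_gt_0.7`.
#' @export
compare_models <- function(fits) {
  if (!is.list(fits) || length(fits) < 1) stop_input("'fits' must be a non-empty list")
  nms <- names(fits)
  if (is.null(nms)) nms <- rep("", length(fits))
  for (i in seq_along(fits)) {
    if (!inherits(fits[[i]], "loo_result"))
      stop_input("entry ", i, " is not a loo_result")
    if (nms[i] == "")
      nms[i] <- if (is.null(fits[[i]]$model)) paste0("model_", i) else fits[[i]]$model
  }
  n_obs <- vapply(fits, `[[`, numeric(1), "n_obs")
  if (length(unique(n_obs)) > 1)
    stop_input("fits have different observation counts: not the same dataset")
  fps <- lapply(fits, `[[`, "fingerprint")
  fps <- unique(unlist(fps[!vapply(fps, is.null, TRUE)]))
  if (length(fps) > 1)
    stop_input("fits carry different dataset fingerprints: not the same dataset")
  elpd <- vapply(fits, `[[`, numeric(1), "elpd")
  ord <- order(elpd, decreasing = TRUE)
  best <- fits[[ord[1]]]
  rows <- lapply(ord, function(i) {
    f <- fits[[i]]
    dpt <- best$pointwise - f$pointwise
    d <- sum(dpt)
    se_d <- sqrt(f$n_obs * stats::var(dpt))
    data.frame(model = nms[i], elpd = f$elpd, se = f$se,
               elpd_diff = d, se_diff = se_d,
               verdict = if (d == 0) "best" else if (d <= se_d) "indistinguishable" else "worse",
               n_pareto_k_gt_0.7 = sum(is.finite(f$pareto_k) & f$pareto_k > 0.7))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("model_comparison", "data.frame")
  out
}
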