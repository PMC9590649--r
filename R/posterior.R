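#' Posterior-mean regression curve with HDI and posterior-predictive bands
#'
#' For each grid value of `n`, the regression curve `f(n)` is evaluated at
#' every posterior draw; the band table reports the mean of those values,
#' their 95% HDI, and the 95% HDI of one posterior-predictive draw
#' `k ~ Normal(f(n), sigma(n))` per posterior draw. Draws for which `f(n)`
#' is undefined at a grid point (diminishing-returns domain violation) are
#' excluded at that point and counted; a warning is raised when more than 1%
#' of draws are excluded anywhere.
#'
#' @param samples a [sample_posterior()] result.
#' @param grid numeric vector of `n` (log10 cell number) values; default is
#'   200 evenly spaced points spanning `grid_range`.
#' @param grid_range range of `n` used when `grid` is `NULL`.
#' @param prob band coverage (default 0.95).
#' @param seed optional seed for the posterior-predictive simulation.
#' @return A `data.frame` of class `curve_band` with columns `n`, `mean`,
#'   `hdi_lo`, `hdi_hi`, `ppd_lo`, `ppd_hi`, `n_excluded`.
#' @export
posterior_curve <- function(samples, grid = NULL, grid_range = c(0.3, 14),
                            prob = 0.95, seed = NULL) {
  stopifnot(inherits(samples, "posterior_samples"))
  if (is.null(grid)) grid <- seq(grid_range[1], grid_range[2], length.out = 200)
  if (!is.null(seed)) set.seed(seed)
  spec <- samples$spec
  th <- flatten_draws(samples)
  D <- nrow(th)
  out <- lapply(grid, function(ng) {
    mu <- model_mean_draws(spec, ng, th)
    sigma <- model_sd_draws(spec, ng, th)
    ok <- is.finite(mu) & is.finite(sigma) & sigma > 0
    excl <- sum(!ok)
    if (sum(ok) < 2) {
      return(data.frame(n = ng, mean = NA_real_, hdi_lo = NA_real_,
                        hdi_hi = NA_real_, ppd_lo = NA_real_, ppd_hi = NA_real_,
                        n_excluded = excl))
    }
    mu_ok <- mu[ok]
    h <- if (length(unique(mu_ok)) == 1) rep(mu_ok[1], 2) else hdi(mu_ok, prob)
    ksim <- stats::rnorm(sum(ok), mu_ok, sigma[ok])
    hp <- hdi(ksim, prob)
    data.frame(n = ng, mean = mean(mu_ok), hdi_lo = h[1], hdi_hi = h[2],
               ppd_lo = hp[1], ppd_hi = hp[2], n_excluded = excl)
  })
  res <- do.call(rbind, out)
  if (any(res$n_excluded > 0.01 * D)) {
    warning(sprintf("more than 1%% of posterior draws excluded at %d grid point(s)",
                    sum(res$n_excluded > 0.01 * D)), call. = FALSE)
  }
  class(res) <- c("curve_band", "data.frame")
  res
}

## mean / sd over all draws at one grid point; th is draws x parameter matrix
model_mean_draws <- function(spec, ng, th) {
  if (spec$mean_kind == "double_power_law") {
    ifelse(ng < th[, "n_bp"],
           th[, "k0"] + th[, "s_small"] * ng,
           th[, "k0"] + th[, "s_small"] * th[, "n_bp"] +
             th[, "s_large"] * (ng - th[, "n_bp"]))
  } else {
    x <- th[, "A"] + th[, "B"] * ng
    ifelse(x > 0, log10(pmax(x, .Machine$double.xmin)), NaN)
  }
}

model_sd_draws <- function(spec, ng, th) {
  if (spec$sd_kind == "constant") th[, "Sigma"] else th[, "Sigma0"] + th[, "s_Sigma"] * ng
}

#' Posterior summary table
#'
#' One row per parameter: posterior mean over all chains and draws, 95% HDI
#' bounds, split-R-hat and effective sample size.
#'
#' @param samples a [sample_posterior()] result.
#' @param prob HDI coverage (default 0.95).
#' @return A `data.frame` with columns `parameter`, `mean`, `hdi_lo`,
#'   `hdi_hi`, `rhat`, `ess`.
#' @export
summarize_posterior <- function(samples, prob = 0.95) {
  stopifnot(inherits(samples, "posterior_samples"))
  th <- flatten_draws(samples)
  rows <- lapply(colnames(th), function(pn) {
    x <- th[, pn]
    h <- if (length(unique(x)) == 1) c(x[1], x[1]) else hdi(x, prob)
    data.frame(parameter = pn, mean = mean(x), hdi_lo = h[1], hdi_hi = h[2],
               rhat = samples$rhat[[pn]], ess = samples$ess[[pn]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
summary.posterior_samples <- function(object, prob = 0.95, ...) {
  summarize_posterior(object, prob = prob)
}

#' Write a posterior summary as a JSON document
#'
#' Mirrors the layout of a parameter-estimates table: per parameter the
#' posterior mean and HDI bounds, plus the model name and diagnostics.
#'
#' @param samples a [sample_posterior()] result.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(samples, path) {
  s <- summarize_posterior(samples)
  doc <- list(model = samples$spec$name,
              n_obs = samples$n_obs,
              converged = samples$converged,
              parameters = lapply(seq_len(nrow(s)), function(i) {
                list(name = s$parameter[i], mean = s$mean[i],
                     hdi_95 = c(s$hdi_lo[i], s$hdi_hi[i]),
                     rhat = s$rhat[i], ess = s$ess[i])
              }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
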