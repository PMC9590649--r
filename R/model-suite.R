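#' Specify one of the four allometry regression models
#'
#' All models describe the log10 cell-type number `k` as normally distributed
#' around a mean curve of the log10 cell number `n`, fit entirely in double
#' log-space. The mean is either a double power law (piecewise linear in
#' log-log space with a breakpoint) or the diminishing-returns curve
#' \eqn{f(n) = \log_{10}(A + B n)}; the standard deviation is either constant
#' or increases linearly with `n`.
#'
#' Priors are fixed:
#' \itemize{
#'   \item `k0` ~ Uniform(-0.5, 0.5)
#'   \item `s_small`, `s_large`, `A`, `B` ~ Normal(0, 20)
#'   \item `n_bp` ~ Normal(5, 2)
#'   \item `Sigma` ~ HalfCauchy(scale 10): a Cauchy at location 0 with
#'     half-width-at-half-maximum 10, truncated to positive values
#'   \item `Sigma0`, `s_Sigma` ~ HalfNormal(sd 1)
#' }
#'
#' @param mean_kind `"double_power_law"` or `"diminishing_returns"`.
#' @param sd_kind `"constant"` or `"variable"`.
#' @return An object of class `model_spec` with elements `mean_kind`,
#'   `sd_kind`, `name` (one of `dpl_const`, `dpl_var`, `dr_const`, `dr_var`),
#'   `par_names`, and the prior definitions.
#' @examples
#' model_spec("diminishing_returns", "constant")
#' @export
model_spec <- function(mean_kind = c("double_power_law", "diminishing_returns"),
                       sd_kind = c("constant", "variable")) {
  mean_kind <- match.arg(mean_kind)
  sd_kind <- match.arg(sd_kind)
  mean_pars <- if (mean_kind == "double_power_law") {
    c("k0", "s_small", "n_bp", "s_large")
  } else {
    c("A", "B")
  }
  sd_pars <- if (sd_kind == "constant") "Sigma" else c("Sigma0", "s_Sigma")
  priors <- list(
    k0      = list(dist = "uniform", lo = -0.5, hi = 0.5),
    s_small = list(dist = "normal", mu = 0, sd = 20),
    n_bp    = list(dist = "normal", mu = 5, sd = 2),
    s_large = list(dist = "normal", mu = 0, sd = 20),
    A       = list(dist = "normal", mu = 0, sd = 20),
    B       = list(dist = "normal", mu = 0, sd = 20),
    Sigma   = list(dist = "halfcauchy", scale = 10),
    Sigma0  = list(dist = "halfnormal", sd = 1),
    s_Sigma = list(dist = "halfnormal", sd = 1)
  )
  par_names <- c(mean_pars, sd_pars)
  structure(list(
    mean_kind = mean_kind,
    sd_kind = sd_kind,
    name = paste0(if (mean_kind == "double_power_law") "dpl" else "dr",
                  if (sd_kind == "constant") "_const" else "_var"),
    par_names = par_names,
    priors = priors[par_names]
  ), class = "model_spec")
}

#' Look up a model specification by its short name
#'
#' @param name one of `"dpl_const"`, `"dpl_var"`, `"dr_const"`, `"dr_var"`.
#' @return A [model_spec()].
#' @export
model_spec_by_name <- function(name) {
  switch(name,
         dpl_const = model_spec("double_power_law", "constant"),
         dpl_var   = model_spec("double_power_law", "variable"),
         dr_const  = model_spec("diminishing_returns", "constant"),
         dr_var    = model_spec("diminishing_returns", "variable"),
         stop_input("unknown model '", name,
                    "'; expected one of dpl_const, dpl_var, dr_const, dr_var"))
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("Allometry model '%s': %s mean, %s sd\n", x$name,
              gsub("_", " ", x$mean_kind), x$sd_kind))
  cat("  parameters:", paste(x$par_names, collapse = ", "), "\n")
  invisible(x)
}

as_param_vector <- function(spec, params) {
  p <- unlist(params)
  missing <- setdiff(spec$par_names, names(p))
  if (length(missing) > 0)
    stop_input("missing parameter(s) for model ", spec$name, ": ",
               paste(missing, collapse = ", "))
  p[spec$par_names]
}

#' Mean curve of the double power law
#'
#' Piecewise linear relation between log10 cell number `n` and log10
#' cell-type number: slope `s_small` below the breakpoint `n_bp`, slope
#' `s_large` at and above it, continuous at the breakpoint.
#'
#' @param n log10 cell numbers; vectorized.
#' @param params named vector or list with `k0`, `s_small`, `n_bp`, `s_large`.
#' @return Expected log10 cell-type numbers.
#' @export
mean_double_power_law <- function(n, params) {
  p <- unlist(params)
  ifelse(n < p[["n_bp"]],
         p[["k0"]] + p[["s_small"]] * n,
         p[["k0"]] + p[["s_small"]] * p[["n_bp"]] + p[["s_large"]] * (n - p[["n_bp"]]))
}

#' Mean curve of the diminishing-returns model
#'
#' \eqn{f(n) = \log_{10}(A + B n)}: the log of the cell-type capacity implied
#' by the segregation-event fitness model. Where `A + B*n <= 0` the curve is
#' undefined and `NaN` is returned; the likelihood treats such points as log
#' density `-Inf` so that samplers reject the parameter point rather than
#' error out.
#'
#' @param n log10 cell numbers; vectorized.
#' @param params named vector or list with `A`, `B`.
#' @return Expected log10 cell-type numbers (`NaN` where undefined).
#' @export
mean_diminishing_returns <- function(n, params) {
  p <- unlist(params)
  x <- p[["A"]] + p[["B"]] * n
  ifelse(x > 0, log10(pmax(x, .Machine$double.xmin)), NaN)
}

#' Standard-deviation function of the observation model
#'
#' Constant variant: returns `Sigma` for every `n`. Variable variant:
#' \eqn{g(n) = \Sigma_0 + s_\Sigma n}, the spread of log cell-type numbers
#' growing linearly with log cell number. Non-positive values are returned
#' as-is; the likelihood maps them to `-Inf` log density.
#'
#' @param n log10 cell numbers; vectorized.
#' @param noise named vector or list with either `Sigma` or
#'   (`Sigma0`, `s_Sigma`).
#' @return Standard deviations of `k` at each `n`.
#' @export
sd_function <- function(n, noise) {
  p <- unlist(noise)
  if ("Sigma" %in% names(p)) {
    rep(p[["Sigma"]], length(n))
  } else if (all(c("Sigma0", "s_Sigma") %in% names(p))) {
    p[["Sigma0"]] + p[["s_Sigma"]] * n
  } else {
    stop_input("'noise' must contain either 'Sigma' or ('Sigma0', 's_Sigma')")
  }
}

model_mean <- function(spec, n, p) {
  if (spec$mean_kind == "double_power_law") {
    mean_double_power_law(n, p)
  } else {
    mean_diminishing_returns(n, p)
  }
}

model_sd <- function(spec, n, p) sd_function(n, p)

#' Per-observation log likelihood
#'
#' Element `i` is the natural-log normal density of `k_i` at mean `f(n_i)`
#' and standard deviation `sigma(n_i)`. Domain violations (undefined mean,
#' non-positive sd) yield `-Inf` elements rather than errors, which is
#' equivalent to truncating the prior to the valid parameter region.
#'
#' @param dataset an [allometry_dataset()] (non-empty).
#' @param spec a [model_spec()].
#' @param params named vector or list with the model's mean and noise
#'   parameters.
#' @return Numeric vector of per-observation log densities (natural log).
#' @export
pointwise_log_likelihood <- function(dataset, spec, params) {
  stopifnot(inherits(dataset, "allometry_dataset"), inherits(spec, "model_spec"))
  if (nrow(dataset) == 0) stop_input("dataset is empty")
  p <- as_param_vector(spec, params)
  mu <- model_mean(spec, dataset$n, p)
  sigma <- model_sd(spec, dataset$n, p)
  ok <- is.finite(mu) & is.finite(sigma) & sigma > 0
  ll <- rep(-Inf, nrow(dataset))
  ll[ok] <- stats::dnorm(dataset$k[ok], mu[ok], sigma[ok], log = TRUE)
  ll
}

prior_log_density <- function(prior, x) {
  switch(prior$dist,
         uniform = stats::dunif(x, prior$lo, prior$hi, log = TRUE),
         normal = stats::dnorm(x, prior$mu, prior$sd, log = TRUE),
         halfcauchy = ifelse(x > 0,
                             log(2) + stats::dcauchy(x, 0, prior$scale, log = TRUE),
                             -Inf),
         halfnormal = ifelse(x > 0,
                             log(2) + stats::dnorm(x, 0, prior$sd, log = TRUE),
                             -Inf),
         stop_input("unknown prior distribution ", prior$dist))
}

prior_quantile <- function(prior, p) {
  switch(prior$dist,
         uniform = stats::qunif(p, prior$lo, prior$hi),
         normal = stats::qnorm(p, prior$mu, prior$sd),
         halfcauchy = stats::qcauchy((1 + p) / 2, 0, prior$scale),
         halfnormal = stats::qnorm((1 + p) / 2, 0, prior$sd))
}

prior_sample <- function(prior, n) {
  switch(prior$dist,
         uniform = stats::runif(n, prior$lo, prior$hi),
         normal = stats::rnorm(n, prior$mu, prior$sd),
         halfcauchy = abs(stats::rcauchy(n, 0, prior$scale)),
         halfnormal = abs(stats::rnorm(n, 0, prior$sd)))
}

#' Joint log prior density
#'
#' Sum of the independent log prior densities of all parameters of the model;
#' `-Inf` outside any parameter's support (the half distributions carry the
#' factor-2 normalization on the positive half-line).
#'
#' @inheritParams pointwise_log_likelihood
#' @return Scalar log density (natural log).
#' @export
log_prior <- function(spec, params) {
  stopifnot(inherits(spec, "model_spec"))
  p <- as_param_vector(spec, params)
  sum(vapply(spec$par_names,
             function(nm) prior_log_density(spec$priors[[nm]], p[[nm]]),
             numeric(1)))
}

#' Unnormalized log posterior
#'
#' `sum(pointwise_log_likelihood) + log_prior`, up to the normalizing
#' constant. `-Inf` from either component propagates. With an empty dataset
#' the likelihood term is dropped, so the posterior reduces to the prior
#' (used for prior-only sampling).
#'
#' @inheritParams pointwise_log_likelihood
#' @return Scalar log density (natural log).
#' @export
log_posterior <- function(dataset, spec, params) {
  lp <- log_prior(spec, params)
  if (!is.finite(lp)) return(lp)
  if (nrow(dataset) == 0) return(lp)
  lp + sum(pointwise_log_likelihood(dataset, spec, params))
}

#' Serialize / deserialize a parameter point as flat JSON
#'
#' @param params named vector or list of parameter values.
#' @param path JSON file path.
#' @return `params_to_json` returns `path` invisibly; `params_from_json`
#'   returns a named numeric vector.
#' @export
params_to_json <- function(params, path) {
  jsonlite::write_json(as.list(unlist(params)), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname params_to_json
#' @export
params_from_json <- function(path) {
  unlist(jsonlite::read_json(path, simplifyVector = TRUE))
}
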