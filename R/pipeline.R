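#' Fit one allometry regression model
#'
#' Convenience wrapper: resolves the model name, applies the per-model
#' default `target_accept` (0.99 for the diminishing-returns/constant-sd
#' model, which is the hardest geometry; 0.8 otherwise — recorded for
#' interface parity, see [sampler_config()]), samples the posterior, and
#' attaches the pointwise log-likelihood matrix and its PSIS-LOO estimate.
#'
#' @param dataset an [allometry_dataset()] with at least 3 rows.
#' @param model model name (`dpl_const`, `dpl_var`, `dr_const`, `dr_var`) or
#'   a [model_spec()].
#' @param chains,tune,draws,seed passed to [sampler_config()].
#' @param target_accept `NULL` uses the per-model default.
#' @param temperatures `NULL` uses the per-model default: a 4-rung parallel
#'   tempering ladder for the double-power-law models, whose breakpoint
#'   posterior can be bimodal (breakpoint inside vs. below the sampled size
#'   range), and a single temperature for the unimodal diminishing-returns
#'   models.
#' @return An object of class `allometry_fit`: list with `samples`
#'   ([sample_posterior()] result), `loo` ([loo_elpd()] result), `summary`
#'   (from [summarize_posterior()]) and `dataset`.
#' @export
fit_allometry_model <- function(dataset, model = "dr_const", chains = 2,
                                tune = 2000, draws = 10000,
                                target_accept = NULL, seed = 1L,
                                temperatures = NULL) {
  stopifnot(inherits(dataset, "allometry_dataset"))
  if (nrow(dataset) < 3)
    stop_input("dataset too small to fit (", nrow(dataset), " row(s); need >= 3)")
  spec <- if (inherits(model, "model_spec")) model else model_spec_by_name(model)
  if (is.null(target_accept))
    target_accept <- if (spec$name == "dr_const") 0.99 else 0.8
  if (is.null(temperatures))
    temperatures <- if (spec$mean_kind == "double_power_law")
      c(1, 0.45, 0.2, 0.09, 0.04) else 1
  cfg <- sampler_config(chains = chains, tune = tune, draws = draws,
                        target_accept = target_accept, seed = seed,
                        temperatures = temperatures)
  samples <- sample_posterior(dataset, spec, cfg)
  ll <- log_likelihood_matrix(samples, dataset)
  loo <- loo_elpd(ll, model = spec$name,
                  fingerprint = dataset_fingerprint(dataset))
  structure(list(samples = samples, loo = loo,
                 summary = summarize_posterior(samples),
                 loglik = ll, dataset = dataset),
            class = "allometry_fit")
}

#' @export
print.allometry_fit <- function(x, ...) {
  print(x$samples)
  print(x$loo)
  invisible(x)
}

resolve_input <- function(input, cells_col = NULL, types_col = NULL) {
  if (inherits(input, "allometry_dataset")) {
    list(dataset = input, description = "in-memory dataset")
  } else if (inherits(input, "generator_config")) {
    list(dataset = generate_dataset(input),
         description = sprintf("synthetic (%s, size %d, seed %d)",
                               input$true_model$name, input$size, input$seed))
  } else if (is.character(input) && length(input) == 1) {
    list(dataset = read_allometry_csv(input, cells_col, types_col),
         description = input)
  } else {
    stop_input("'input' must be a CSV path, an allometry_dataset or a generator_config")
  }
}

write_run_manifest <- function(out_dir, input_description, seed, models,
                               sampler = NULL, extra = list()) {
  doc <- c(list(tool = "cellallometry",
                version = as.character(utils::packageVersion("cellallometry")),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                input = input_description,
                seed = seed,
                models = models,
                sampler = sampler),
           extra)
  jsonlite::write_json(doc, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file.path(out_dir, "run_manifest.json"))
}

#' Fit one model and write its outputs
#'
#' Pipeline stage behind the `fit` command: reads the data, fits the chosen
#' model, and writes `summary_<model>.json`, `samples_<model>.csv` and a run
#' manifest into `out_dir`.
#'
#' @param input CSV path, [allometry_dataset()] or [generator_config()].
#' @param model model name (see [fit_allometry_model()]).
#' @param out_dir output directory (created if missing).
#' @param cells_col,types_col CSV column overrides.
#' @inheritParams fit_allometry_model
#' @return The `allometry_fit`, invisibly.
#' @export
run_fit <- function(input, model = "dr_const", out_dir = ".", chains = 2,
                    tune = 2000, draws = 10000, target_accept = NULL,
                    seed = 1L, cells_col = NULL, types_col = NULL) {
  src <- resolve_input(input, cells_col, types_col)
  message("[cellallometry] fitting model ", model, " to ", src$description,
          " (", nrow(src$dataset), " organisms)")
  fit <- fit_allometry_model(src$dataset, model, chains = chains, tune = tune,
                             draws = draws, target_accept = target_accept,
                             seed = seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_summary_json(fit$samples, file.path(out_dir, paste0("summary_", fit$samples$spec$name, ".json")))
  write_samples_csv(fit$samples, file.path(out_dir, paste0("samples_", fit$samples$spec$name, ".csv")))
  write_run_manifest(out_dir, src$description, seed,
                     models = fit$samples$spec$name,
                     sampler = unclass(fit$samples$config))
  if (!fit$samples$converged)
    warning("fit did not pass convergence diagnostics; see summary JSON",
            call. = FALSE)
  invisible(fit)
}

#' Fit all four models, compare them, and render the panel figure
#'
#' Pipeline stage behind the `compare` command: fits the double power law and
#' diminishing-returns models with constant and variable sd, computes
#' PSIS-LOO for each, writes the ranked comparison (CSV + JSON), per-model
#' summaries, pointwise log-likelihood matrices, a four-panel figure
#' (data, posterior-mean curve, 95% HDI band, 95% posterior-predictive band,
#' elpd annotation) and a run manifest.
#'
#' @inheritParams run_fit
#' @param figure_format `"pdf"` (default) or `"svg"`; vector output either way.
#' @return Named list with `fits`, `comparison` and `curves`, invisibly.
#' @export
run_compare <- function(input, out_dir = ".", chains = 2, tune = 2000,
                        draws = 10000, seed = 1L, cells_col = NULL,
                        types_col = NULL, figure_format = c("pdf", "svg")) {
  figure_format <- match.arg(figure_format)
  src <- resolve_input(input, cells_col, types_col)
  dataset <- src$dataset
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  models <- c("dpl_const", "dr_const", "dpl_var", "dr_var")
  fits <- list()
  for (m in models) {
    message("[cellallometry] fitting ", m)
    fits[[m]] <- fit_allometry_model(dataset, m, chains = chains, tune = tune,
                                     draws = draws, seed = seed)
    write_summary_json(fits[[m]]$samples,
                       file.path(out_dir, paste0("summary_", m, ".json")))
    utils::write.csv(fits[[m]]$loglik,
                     file.path(out_dir, paste0("loglik_", m, ".csv")),
                     row.names = FALSE)
  }
  comparison <- compare_models(lapply(fits, `[[`, "loo"))
  utils::write.csv(comparison, file.path(out_dir, "comparison.csv"), row.names = FALSE)
  jsonlite::write_json(comparison, file.path(out_dir, "comparison.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  pad <- 0.02 * diff(range(dataset$n))
  grid <- seq(min(dataset$n) - pad, max(dataset$n) + pad, length.out = 200)
  curves <- lapply(fits, function(f)
    posterior_curve(f$samples, grid = grid, seed = seed))
  fig_path <- file.path(out_dir, paste0("model_panel.", figure_format))
  p <- plot_model_grid(dataset, curves, fits)
  dev <- if (figure_format == "pdf") grDevices::pdf else grDevices::svg
  dev(fig_path, width = 9, height = 7)
  print(p)
  grDevices::dev.off()
  write_run_manifest(out_dir, src$description, seed, models = models,
                     sampler = list(chains = chains, tune = tune, draws = draws))
  message("[cellallometry] best model by elpd: ", comparison$model[1])
  invisible(list(fits = fits, comparison = comparison, curves = curves))
}

#' Write a synthetic dataset and its manifest
#'
#' @param config a [generator_config()].
#' @param out_dir output directory.
#' @return Path of the written CSV, invisibly.
#' @export
run_simulate <- function(config, out_dir = ".") {
  stopifnot(inherits(config, "generator_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  d <- generate_dataset(config)
  path <- file.path(out_dir, "synthetic_dataset.csv")
  write_allometry_csv(d, path)
  generator_config_to_json(config, file.path(out_dir, "generator_config.json"))
  write_run_manifest(out_dir, "synthetic generator", config$seed,
                     models = config$true_model$name,
                     extra = list(generator = list(size = config$size,
                                                   n_range = config$n_range)))
  message("[cellallometry] wrote ", config$size, " organisms to ", path)
  invisible(path)
}

#' Tabulate theoretical capacity against the forward simulation
#'
#' Evaluates the closed-form cell-type capacity and the discrete
#' accumulation simulator over a log-spaced grid of organism sizes and flags
#' any disagreement larger than one type. A benefit decay factor `b` very
#' close to 1 makes the capacity slope `B = (gamma - delta)/log10(b)` blow
#' up; such parameter sets are flagged as near-singular.
#'
#' @param params a [fitness_params()] object.
#' @param N_range range of cell numbers (default `c(10, 1e12)`).
#' @param points number of grid points (default 12).
#' @param out_dir optional output directory for `theory_table.csv` and a
#'   manifest.
#' @return A `data.frame` with columns `N`, `capacity`, `simulated`,
#'   `abs_diff`, `flag`.
#' @export
run_theory <- function(params, N_range = c(10, 1e12), points = 12,
                       out_dir = NULL) {
  stopifnot(inherits(params, "fitness_params"))
  if (log10(params$b) < 1e-3)
    warning("b is within 0.1% of 1: capacity slope B = (gamma-delta)/log10(b) ",
            "is near-singular", call. = FALSE)
  cf <- closed_form_coefficients(params)
  N <- 10^seq(log10(N_range[1]), log10(N_range[2]), length.out = points)
  cap <- capacity(N, cf)
  sim <- vapply(N, function(x) as.integer(simulate_accumulation(x, params)),
                integer(1))
  diff <- abs(sim - pmax(1, cap))
  out <- data.frame(N = N, capacity = cap, simulated = sim,
                    abs_diff = diff, flag = diff > 1)
  if (any(out$flag))
    warning("simulation and closed form disagree by more than one type at ",
            sum(out$flag), " grid point(s)", call. = FALSE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out, file.path(out_dir, "theory_table.csv"), row.names = FALSE)
    write_run_manifest(out_dir, "theory table", NA_integer_, models = "fitness_model",
                       extra = list(params = unclass(params)))
  }
  out
}

#' Plot one model's curve band over the data
#'
#' @param dataset an [allometry_dataset()].
#' @param curve a [posterior_curve()] result.
#' @param title optional panel title.
#' @return A ggplot object: data points, posterior-mean curve, 95% HDI band
#'   of `f(n)` and 95% posterior-predictive band, on log10-log10 axes.
#' @export
plot_curve_band <- function(dataset, curve, title = NULL) {
  stopifnot(inherits(curve, "curve_band"))
  ggplot2::ggplot() +
    ggplot2::geom_ribbon(data = curve,
                         ggplot2::aes(x = n, ymin = ppd_lo,
                                      ymax = ppd_hi),
                         fill = "darkorange", alpha = 0.3) +
    ggplot2::geom_ribbon(data = curve,
                         ggplot2::aes(x = n, ymin = hdi_lo,
                                      ymax = hdi_hi),
                         fill = "steelblue", alpha = 0.45) +
    ggplot2::geom_line(data = curve, ggplot2::aes(x = n, y = mean),
                       linewidth = 0.8) +
    ggplot2::geom_point(data = dataset, ggplot2::aes(x = n, y = k),
                        shape = 1, size = 1.8) +
    ggplot2::labs(x = expression(log[10] ~ "number of cells"),
                  y = expression(log[10] ~ "number of cell types"),
                  title = title) +
    ggplot2::theme_minimal()
}

#' Four-panel model figure
#'
#' One panel per fitted model with its curve bands and an elpd annotation.
#'
#' @param dataset an [allometry_dataset()].
#' @param curves named list of [posterior_curve()] results.
#' @param fits named list of [fit_allometry_model()] results (same names).
#' @return A ggplot object faceted by model.
#' @export
plot_model_grid <- function(dataset, curves, fits) {
  panels <- names(curves)
  band_df <- do.call(rbind, lapply(panels, function(m) {
    cbind(model = m, as.data.frame(curves[[m]]))
  }))
  ann <- do.call(rbind, lapply(panels, function(m) {
    data.frame(model = m,
               label = sprintf("elpd %.2f (se %.2f)",
                               fits[[m]]$loo$elpd, fits[[m]]$loo$se))
  }))
  pts <- merge(as.data.frame(dataset), data.frame(model = panels))
  ggplot2::ggplot() +
    ggplot2::geom_ribbon(data = band_df,
                         ggplot2::aes(x = n, ymin = ppd_lo,
                                      ymax = ppd_hi),
                         fill = "darkorange", alpha = 0.3) +
    ggplot2::geom_ribbon(data = band_df,
                         ggplot2::aes(x = n, ymin = hdi_lo,
                                      ymax = hdi_hi),
                         fill = "steelblue", alpha = 0.45) +
    ggplot2::geom_line(data = band_df, ggplot2::aes(x = n, y = mean),
                       linewidth = 0.7) +
    ggplot2::geom_point(data = pts, ggplot2::aes(x = n, y = k),
                        shape = 1, size = 1.4) +
    ggplot2::geom_text(data = ann,
                       ggplot2::aes(x = -Inf, y = Inf, label = label),
                       hjust = -0.05, vjust = 1.5, size = 3) +
    ggplot2::facet_wrap(~model) +
    ggplot2::labs(x = expression(log[10] ~ "number of cells"),
                  y = expression(log[10] ~ "number of cell types")) +
    ggplot2::theme_minimal()
}
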