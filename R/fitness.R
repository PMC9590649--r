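#' Parameters of the cost/benefit model of cell-type segregation
#'
#' A new cell type arises by functional segregation of an existing type. The
#' event carries a fitness cost that scales as a power law with total cell
#' number, \eqn{\Delta f_{cost} = c N^\delta}, and a fitness benefit that also
#' scales as a power law but is cut by a constant factor \eqn{b > 1} for every
#' cell type the organism already has,
#' \eqn{\Delta f_{benefit} = a N^\gamma b^{-K}}.
#'
#' @param a benefit amplitude, > 0.
#' @param b per-event benefit decay factor, > 1 (each segregation event
#'   divides the benefit of the next one by `b`).
#' @param c cost amplitude, > 0.
#' @param gamma benefit exponent on cell number.
#' @param delta cost exponent on cell number. For a cell-type capacity that
#'   grows with organism size, `gamma > delta`; a warning is issued otherwise.
#' @return An object of class `fitness_params`.
#' @seealso [delta_fitness()], [closed_form_coefficients()],
#'   [simulate_accumulation()]
#' @examples
#' p <- fitness_params(a = 1, b = 10, c = 1, gamma = 1, delta = 0)
#' closed_form_coefficients(p)
#' @export
fitness_params <- function(a, b, c, gamma, delta) {
  for (nm in c("a", "b", "c", "gamma", "delta")) {
    v <- get(nm, inherits = FALSE)
    if (!is_scalar_number(v)) stop_input("'", nm, "' must be a finite scalar")
  }
  if (a <= 0) stop_input("'a' must be > 0")
  if (c <= 0) stop_input("'c' must be > 0")
  if (b <= 1) stop_input("'b' must be > 1: the benefit must shrink at each segregation event")
  if (gamma <= delta) {
    warning("gamma <= delta: cell-type capacity does not increase with cell number",
            call. = FALSE)
  }
  structure(list(a = a, b = b, c = c, gamma = gamma, delta = delta),
            class = "fitness_params")
}

#' @export
print.fitness_params <- function(x, ...) {
  cat("Segregation-event fitness model\n")
  cat(sprintf("  benefit: %g * N^%g * %g^-K\n", x$a, x$gamma, x$b))
  cat(sprintf("  cost:    %g * N^%g\n", x$c, x$delta))
  cf <- closed_form_coefficients(x)
  cat(sprintf("  capacity: K = %.4g + %.4g * log10(N)\n", cf$A, cf$B))
  invisible(x)
}

#' Serialize / deserialize fitness parameters as flat JSON
#'
#' @param params a [fitness_params()] object.
#' @param path file path; for `fitness_params_from_json`, an existing JSON
#'   file with keys `a`, `b`, `c`, `gamma`, `delta`.
#' @return `fitness_params_to_json` returns `path` invisibly;
#'   `fitness_params_from_json` returns a `fitness_params` object.
#' @export
fitness_params_to_json <- function(params, path) {
  stopifnot(inherits(params, "fitness_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname fitness_params_to_json
#' @export
fitness_params_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fitness_params(x$a, x$b, x$c, x$gamma, x$delta)
}

check_N <- function(N) {
  if (!is.numeric(N) || length(N) < 1L || any(!is.finite(N)) || any(N <= 0))
    stop_input("'N' must be finite and > 0")
  invisible(N)
}

#' Fitness change of one cell-type segregation event
#'
#' \eqn{\Delta f = a N^\gamma b^{-K} - c N^\delta}: the net fitness change of
#' adding one cell type to an organism of `N` cells that already has `K` cell
#' types. The event can fix in the population only if the change is
#' non-negative.
#'
#' @param N total cell number (> 0, real-valued allowed); vectorized.
#' @param K number of existing cell types (>= 0); vectorized.
#' @param params a [fitness_params()] object.
#' @param component `"net"` (default) returns benefit minus cost;
#'   `"benefit"` and `"cost"` return the two terms separately.
#' @return Numeric vector of fitness changes (dimensionless).
#' @examples
#' p <- fitness_params(a = 1, b = 2, c = 1, gamma = 1, delta = 0)
#' delta_fitness(1000, K = 0:12, p)
#' @export
delta_fitness <- function(N, K, params,
                          component = c("net", "benefit", "cost")) {
  stopifnot(inherits(params, "fitness_params"))
  component <- match.arg(component)
  check_N(N)
  if (!is.numeric(K) || any(!is.finite(K)) || any(K < 0))
    stop_input("'K' must be finite and >= 0")
  benefit <- params$a * N^params$gamma * params$b^(-K)
  cost <- params$c * N^params$delta
  switch(component,
         net = benefit - cost,
         benefit = benefit + 0 * K * N,   # recycle to common length
         cost = cost + 0 * K * N)
}

#' Closed-form capacity coefficients
#'
#' Solving \eqn{\Delta f = 0} for `K` gives the largest cell-type count an
#' organism of `N` cells can sustain: \eqn{K = A + B \log_{10} N} with
#' \eqn{A = \log_{10}(a/c)/\log_{10} b} and
#' \eqn{B = (\gamma - \delta)/\log_{10} b}. These are the same `A`, `B` that
#' parameterize the diminishing-returns regression mean
#' \eqn{k = \log_{10}(A + B n)}.
#'
#' @param params a [fitness_params()] object.
#' @return An object of class `capacity_coefficients`: list with elements
#'   `A` and `B`.
#' @export
closed_form_coefficients <- function(params) {
  stopifnot(inherits(params, "fitness_params"))
  lb <- log10(params$b)
  structure(list(A = log10(params$a / params$c) / lb,
                 B = (params$gamma - params$delta) / lb),
            class = "capacity_coefficients")
}

#' @export
print.capacity_coefficients <- function(x, ...) {
  cat(sprintf("Cell-type capacity: K = %.6g + %.6g * log10(N)\n", x$A, x$B))
  invisible(x)
}

#' Real-valued cell-type capacity
#'
#' Evaluates \eqn{K = A + B \log_{10} N}. The value may be below 1 for tiny
#' organisms; callers that display capacities floor them at one, but values
#' used in likelihoods are never silently modified.
#'
#' @param N total cell number (> 0); vectorized.
#' @param coeffs a [closed_form_coefficients()] result, or any list with
#'   elements `A` and `B`.
#' @return Numeric vector of capacities.
#' @export
capacity <- function(N, coeffs) {
  check_N(N)
  coeffs$A + coeffs$B * log10(N)
}

#' Forward simulation of cell-type accumulation
#'
#' Treats the appearance of new cell types as discrete events: starting from a
#' single ancestral type (`K = 1`), the transition `K -> K + 1` is accepted
#' while `delta_fitness(N, K, params) >= 0`, with the benefit evaluated at the
#' current (pre-event) number of types. Serves as a discrete consistency
#' oracle for the closed form: the result is always within one type of
#' `max(1, capacity(N))`.
#'
#' @param N total cell number (> 0), scalar.
#' @param params a [fitness_params()] object.
#' @param k_max safety cap on the number of types (default 100000). Hitting
#'   the cap flags unbounded accumulation at this `N`.
#' @return Integer final cell-type count, with attribute `capped` (logical).
#' @examples
#' p <- fitness_params(a = 1, b = 10, c = 1, gamma = 1, delta = 0)
#' simulate_accumulation(1000, p)  # 4 types: events at K = 1, 2, 3 accepted
#' @export
simulate_accumulation <- function(N, params, k_max = 1e5) {
  stopifnot(inherits(params, "fitness_params"))
  if (!is_scalar_number(N) || N <= 0) stop_input("'N' must be a finite scalar > 0")
  if (!is_scalar_number(k_max) || k_max < 1) stop_input("'k_max' must be >= 1")
  K <- 1L
  while (K < k_max && delta_fitness(N, K, params) >= 0) K <- K + 1L
  capped <- K >= k_max
  if (capped) {
    warning("accumulation cap reached: parameters imply unbounded cell-type gain at N = ",
            format(N), call. = FALSE)
  }
  structure(K, capped = capped)
}
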