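# Seeded synthetic dose-response data emulating the normalized activity
# measurements behind the photoreceptor Hill-curve parameters, plus
# randomized perturbation-protocol fixtures for engine tests.

# The four trial-curve families, on the percent activity scale; x in uM.
.DOSE_CURVES <- list(
  pde_activation = list(
    # light-induced PDE activity vs Ca
    fun = function(x, p) p[["Vmax"]] * .hill_up(x, p[["k12"]], p[["p"]]),
    truth = c(Vmax = 100.01, p = 0.894, k12 = 0.622612),
    half = "k12"),
  gc_inhibition = list(
    # GC activity vs Ca
    fun = function(x, p) 100 * .hill_down(x, p[["k8"]], p[["r"]]),
    truth = c(k8 = 0.05749, r = 1.65),
    half = "k8"),
  cng_cgmp_activation = list(
    # CNG channel activity vs cGMP
    fun = function(x, p) 100 * .hill_up(x, p[["k11"]], p[["n"]]),
    truth = c(k11 = 32.81, n = 4.14),
    half = "k11"),
  cng_ca_inhibition = list(
    # CNG channel activity vs Ca; beta is the Ca-insensitive plateau (%)
    fun = function(x, p) 100 * p[["alpha"]] * .hill_down(x, p[["k10"]], p[["m"]]) +
      p[["beta"]],
    truth = c(alpha = 0.6067, k10 = 0.06357, m = 2.50, beta = 40.07),
    half = "k10")
)

#' Curve kinds available for synthetic dose-response generation
#' @return Character vector of curve-kind names.
#' @export
dose_response_kinds <- function() names(.DOSE_CURVES)

#' Evaluate a dose-response trial function
#'
#' @param curve_kind One of [dose_response_kinds()].
#' @param x Concentrations (uM).
#' @param params Named parameter vector; default: the fitted reference
#'   values.
#' @return Normalized activity in percent.
#' @export
dose_response_curve <- function(curve_kind, x, params = NULL) {
  spec <- .DOSE_CURVES[[curve_kind]]
  if (is.null(spec)) stop("invalid curve kind '", curve_kind, "'; one of: ",
                          paste(names(.DOSE_CURVES), collapse = ", "))
  p <- spec$truth
  if (!is.null(params)) {
    params <- unlist(params)
    bad <- setdiff(names(params), names(p))
    if (length(bad)) stop("unknown parameters for ", curve_kind, ": ",
                          paste(bad, collapse = ", "))
    p[names(params)] <- params
  }
  vapply(x, function(xi) spec$fun(xi, p), numeric(1))
}

#' Generate a synthetic dose-response dataset
#'
#' Draws a noisy normalized dose-response curve: log-spaced concentrations,
#' curve values from the chosen trial function, plus additive homoscedastic
#' Gaussian noise on the percent scale.  Fully reproducible for a fixed
#' seed; noiseless when `noise_sd = 0`.
#'
#' @param curve_kind One of [dose_response_kinds()].
#' @param true_params Named generating parameters (default: the fitted
#'   reference values).
#' @param n_points Number of concentrations (>= 6).
#' @param x_range Concentration range `c(min, max)`; default
#'   0.01-100 x the curve's half-saturation constant.
#' @param noise_sd Noise standard deviation in percent units.
#' @param seed Integer seed (required: no unseeded generation).
#' @return A list of class `dose_response`: `x`, `y`, `curve_kind`,
#'   `true_params`, `noise_sd`, `seed`.
#' @export
#' @examples
#' d <- generate_dose_response("gc_inhibition", noise_sd = 3, seed = 1)
generate_dose_response <- function(curve_kind, true_params = NULL,
                                   n_points = 12, x_range = NULL,
                                   noise_sd = 0, seed) {
  spec <- .DOSE_CURVES[[curve_kind]]
  if (is.null(spec)) stop("invalid curve kind '", curve_kind, "'; one of: ",
                          paste(names(.DOSE_CURVES), collapse = ", "))
  if (n_points < 6L) stop("'n_points' must be >= 6")
  p <- spec$truth
  if (!is.null(true_params)) {
    true_params <- unlist(true_params)
    p[names(true_params)] <- true_params
  }
  if (is.null(x_range)) {
    half <- p[[spec$half]]
    x_range <- c(0.01 * half, 100 * half)
  }
  if (any(x_range <= 0)) stop("'x_range' must be positive")
  x <- exp(seq(log(x_range[1L]), log(x_range[2L]), length.out = n_points))
  y0 <- vapply(x, function(xi) spec$fun(xi, p), numeric(1))
  if (missing(seed)) stop("a seed is required")
  set.seed(as.integer(seed))
  y <- y0 + stats::rnorm(n_points, sd = noise_sd)
  structure(list(x = x, y = y, curve_kind = curve_kind, true_params = p,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "dose_response")
}

#' Fit a trial function to a dose-response dataset
#'
#' Unweighted nonlinear least squares of the dataset's curve family, with
#' asymptotic standard errors from the Jacobian.  On non-convergence the fit
#' restarts from multiplicatively perturbed starting values.
#'
#' @param dataset A `dose_response` (needs at least `#parameters + 2`
#'   points).
#' @param start Optional named starting values; default: the reference
#'   parameter values of the curve family.
#' @param max_restarts Restarts with jittered starts before giving up.
#' @return List with `estimate`, `se` (named vectors), `r2` and the
#'   underlying `nls` fit object.
#' @export
fit_trial_function <- function(dataset, start = NULL, max_restarts = 8) {
  stopifnot(inherits(dataset, "dose_response"))
  spec <- .DOSE_CURVES[[dataset$curve_kind]]
  pn <- names(spec$truth)
  if (length(dataset$x) < length(pn) + 2L) {
    stop("need at least ", length(pn) + 2L, " points to fit ",
         dataset$curve_kind)
  }
  if (is.null(start)) start <- spec$truth
  start <- as.list(start[pn])
  dat <- data.frame(x = dataset$x, y = dataset$y)
  form <- switch(dataset$curve_kind,
    pde_activation = y ~ Vmax * x^p / (k12^p + x^p),
    gc_inhibition = y ~ 100 * k8^r / (k8^r + x^r),
    cng_cgmp_activation = y ~ 100 * x^n / (k11^n + x^n),
    cng_ca_inhibition = y ~ 100 * alpha * k10^m / (k10^m + x^m) + beta)
  fit <- NULL
  st <- start
  for (attempt in 0:max_restarts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = dat, start = st,
                        lower = rep(1e-12, length(st)),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit)) break
    st <- lapply(start, function(v) v * stats::runif(1, 0.3, 3))
  }
  if (is.null(fit)) stop("trial-function fit did not converge after restarts")
  cf <- summary(fit)$coefficients
  ybar <- mean(dataset$y)
  r2 <- 1 - sum(stats::resid(fit)^2) / sum((dataset$y - ybar)^2)
  list(estimate = stats::setNames(cf[, 1L], rownames(cf)),
       se = stats::setNames(cf[, 2L], rownames(cf)),
       r2 = r2, fit = fit)
}

#' Randomized perturbation-protocol fixtures
#'
#' Seeded random but structurally valid protocols for property tests:
#' `"step"` (two phases, jittered onset and height), `"pulse"` (three
#' phases, 10 ms-scale width) and `"three_phase"` (the inflow/outflow
#' alternation profile of the loop-dissection experiments, with jittered
#' heights).
#'
#' @param kind `"step"`, `"pulse"` or `"three_phase"`.
#' @param seed Integer seed.
#' @param parameter Perturbed parameter name for step/pulse fixtures.
#' @return A `perturbation_protocol`.
#' @export
generate_protocol_fixture <- function(kind = c("step", "pulse", "three_phase"),
                                      seed, parameter = "k2") {
  kind <- match.arg(kind)
  if (missing(seed)) stop("a seed is required")
  set.seed(as.integer(seed))
  switch(kind,
    step = {
      onset <- stats::runif(1, 5, 20)
      height <- stats::runif(1, 2, 10)
      step_protocol(onset = onset,
                    overrides = stats::setNames(list(height), parameter),
                    total_time = onset + stats::runif(1, 40, 80),
                    dense_output_step = 0.01)
    },
    pulse = {
      onset <- stats::runif(1, 0.5, 2)
      height <- stats::runif(1, 10, 100)
      width <- stats::runif(1, 0.005, 0.02)
      pulse_protocol(onset = onset,
                     overrides = stats::setNames(list(height), parameter),
                     width = width, total_time = onset + stats::runif(1, 4, 8),
                     dense_output_step = 0.002)
    },
    three_phase = {
      d <- stats::runif(1, 50, 150)
      inflow <- stats::runif(1, 4, 10)
      outflow <- stats::runif(1, 4, 10)
      perturbation_protocol(
        list(list(start = 0, overrides = list(k1 = 0, k2 = 1)),
             list(start = d, overrides = list(k1 = inflow, k2 = 0)),
             list(start = 2 * d, overrides = list(k1 = 0, k2 = outflow))),
        total_time = 3 * d, dense_output_step = 0.01)
    })
}
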