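# Just-noticeable-difference thresholds against backgrounds, and the
# Weber / Stevens law fits.
#
# A threshold stimulus is the step (or pulse) height that drives the
# controlled variable to a prescribed maximum excursion -- here by convention
# 1% of the defended level -- starting from the steady state reached under a
# constant background.  Plotting thresholds against backgrounds probes
# Weber's law (threshold proportional to background, exponent ~1) versus
# Stevens' power law (exponent != 1); both are parametrized here as
# threshold = a * background^n + b.

.excursion_once <- function(model, stimulus, background, stimulus_kind,
                            pulse_width, y0, reference, horizon, step,
                            rtol, atol) {
  base <- list()
  if (!is.null(background)) base[[model$background_name]] <- background
  ov <- base
  ov[[model$perturbation_name]] <- stimulus
  prot <- if (stimulus_kind == "step") {
    perturbation_protocol(list(list(start = 0, overrides = ov)),
                          total_time = horizon, dense_output_step = step)
  } else {
    perturbation_protocol(list(list(start = 0, overrides = ov),
                               list(start = pulse_width, overrides = base)),
                          total_time = horizon, dense_output_step = step)
  }
  traj <- simulate_model(model, prot, initial_state = y0,
                         rtol = rtol, atol = atol)
  met <- response_metrics(traj, reference, onset_time = 0)
  xx <- traj[[met$variable]]
  peak_at_end <- which.max(abs(xx - reference)) > 0.98 * length(xx)
  list(delta = met$delta_max, peak_at_end = peak_at_end)
}

.excursion <- function(model, stimulus, ..., horizon, max_doublings = 3) {
  for (i in 0:max_doublings) {
    r <- .excursion_once(model, stimulus, ..., horizon = horizon)
    if (!r$peak_at_end || i == max_doublings) return(r$delta)
    horizon <- horizon * 2
  }
}

#' Threshold stimulus at a given background
#'
#' Finds, by bracketed root search, the stimulus (step or pulse height of the
#' model's perturbation parameter) whose maximum excursion of the controlled
#' variable equals `target_excursion`.  The system is pre-equilibrated at the
#' baseline stimulus under the given background; every objective evaluation
#' is a full simulation from that state.
#'
#' @param model A `controller_model`.
#' @param background Background value (applied to the model's background
#'   parameter); `NULL` keeps the model's baseline.
#' @param target_excursion Target maximum excursion of the controlled
#'   variable (e.g. 1% of the set-point).
#' @param stimulus_kind `"step"` or `"pulse"`.
#' @param pulse_width Pulse duration (same time units as the model).
#' @param bracket Initial stimulus bracket `c(lo, hi)`; default
#'   `(baseline, 10 * baseline)`, auto-widened by a factor 10 up to twice if
#'   the target is not straddled.
#' @param horizon Simulation window per objective evaluation (auto-doubled
#'   while the excursion peak sits at the window end).
#' @param dense_output_step Output grid spacing for the objective
#'   simulations.
#' @param tol Relative tolerance on the excursion at the returned stimulus:
#'   `|delta_max(s*) - target| < tol * target`.
#' @param rtol,atol Solver tolerances.
#' @return The threshold stimulus value (numeric scalar).
#' @export
#' @examples
#' \donttest{
#' m1 <- motif_preset("fig4")
#' threshold_stimulus(m1, background = 2, target_excursion = 0.03)  # 1.0367
#' }
threshold_stimulus <- function(model, background = NULL, target_excursion,
                               stimulus_kind = c("step", "pulse"),
                               pulse_width = 0.01, bracket = NULL,
                               horizon = NULL, dense_output_step = NULL,
                               tol = 1e-5,
                               rtol = .DEFAULT_RTOL, atol = .DEFAULT_ATOL) {
  stopifnot(inherits(model, "controller_model"))
  stimulus_kind <- match.arg(stimulus_kind)
  if (!is.numeric(target_excursion) || target_excursion <= 0) {
    stop("'target_excursion' must be > 0")
  }
  if (is.null(horizon)) {
    horizon <- if (model$kind == "photoreceptor") 6 else 60
  }
  if (is.null(dense_output_step)) {
    dense_output_step <- if (model$kind == "photoreceptor") 0.002 else 0.005
  }
  baseline <- model$pars[[model$perturbation_name]]
  ov <- list()
  if (!is.null(background)) ov[[model$background_name]] <- background
  y0 <- find_steady_state(model, overrides = ov)
  reference <- if (model$kind == "motif") model$set_point
               else y0[[model$controlled]]

  g <- function(s) {
    .excursion(model, s, background, stimulus_kind, pulse_width, y0,
               reference, dense_output_step, rtol, atol, horizon = horizon) -
      target_excursion
  }
  if (is.null(bracket)) {
    lo <- baseline
    hi <- if (baseline > 0) 10 * baseline else 1
  } else {
    lo <- bracket[1L]; hi <- bracket[2L]
  }
  glo <- if (lo == baseline) -target_excursion else g(lo)
  if (glo > 0) stop("bracket does not straddle the target: excursion at the ",
                    "lower bracket already exceeds the target")
  ghi <- g(hi)
  widenings <- 0
  while (ghi < 0 && widenings < 2) {
    lo <- hi; glo <- ghi
    hi <- hi * 10
    ghi <- g(hi)
    widenings <- widenings + 1
  }
  if (ghi < 0) stop("bracket does not straddle the target even after ",
                    "widening; excursion stays below the target")
  root <- stats::uniroot(g, lower = lo, upper = hi,
                         f.lower = glo, f.upper = ghi,
                         tol = 1e-10 * max(1, hi))$root
  # verify / refine to the requested excursion tolerance
  gr <- g(root)
  iter <- 0
  while (abs(gr) >= tol * target_excursion && iter < 30) {
    if (gr > 0) hi <- root else lo <- root
    root <- (lo + hi) / 2
    gr <- g(root)
    iter <- iter + 1
  }
  if (abs(gr) >= tol * target_excursion) {
    warning("threshold search stopped with |excursion - target| = ",
            signif(abs(gr), 3), "; objective may be non-monotone")
  }
  root
}

#' Threshold curve across backgrounds
#'
#' Runs [threshold_stimulus()] at each background and records, per row, the
#' threshold and the phase-2 steady-state controller level `E_ss` obtained by
#' holding the threshold stimulus constant to convergence (together with its
#' reciprocal).  The "perception" variable of the Weber plots is `E_ss` for
#' activation motifs and `1/E_ss` for derepression motifs.  Per-background
#' failures are recorded in the `error` column and the scan continues.
#'
#' @inheritParams threshold_stimulus
#' @param backgrounds Sorted numeric vector of background values.
#' @param ... Passed on to [threshold_stimulus()].
#' @return A data frame of class `threshold_curve`: `background`,
#'   `threshold`, `E_ss`, `inv_E_ss`, `perception`, `error`.
#' @export
threshold_curve <- function(model, backgrounds, target_excursion,
                            stimulus_kind = "step", ...) {
  stopifnot(inherits(model, "controller_model"))
  if (is.unsorted(backgrounds)) stop("'backgrounds' must be sorted increasingly")
  rows <- lapply(backgrounds, function(bg) {
    tryCatch({
      thr <- threshold_stimulus(model, background = bg,
                                target_excursion = target_excursion,
                                stimulus_kind = stimulus_kind, ...)
      ov <- stats::setNames(list(bg, thr),
                            c(model$background_name, model$perturbation_name))
      ss <- find_steady_state(model, overrides = ov)
      ename <- if ("E" %in% names(ss)) "E"
               else setdiff(names(ss), model$controlled)[1L]
      ess <- ss[[ename]]
      data.frame(background = bg, threshold = thr, E_ss = ess,
                 inv_E_ss = 1 / ess, error = NA_character_)
    }, error = function(e) {
      data.frame(background = bg, threshold = NA_real_, E_ss = NA_real_,
                 inv_E_ss = NA_real_, error = conditionMessage(e))
    })
  })
  out <- do.call(rbind, rows)
  out$perception <- if (identical(model$compensation, "activation"))
    out$E_ss else out$inv_E_ss
  attr(out, "target_excursion") <- target_excursion
  attr(out, "stimulus_kind") <- stimulus_kind
  class(out) <- c("threshold_curve", "data.frame")
  out
}

#' Fit a power law to a threshold curve
#'
#' Nonlinear least squares of `threshold = a * background^n + b` with
#' standard errors from the Jacobian.  Initial guesses: `a` from the
#' endpoint slope, `n = 1`, `b` from the smallest-background threshold; on
#' non-convergence the fit is restarted with perturbed guesses.
#'
#' @param x Backgrounds, or a `threshold_curve` (then `y` is ignored).
#' @param y Thresholds.
#' @param fit_range Optional `c(min, max)` restricting the backgrounds used.
#' @return A list of class `law_fit`: `a`, `n`, `b`, `se_a`, `se_n`, `se_b`,
#'   `r2`, `range`, `n_points`.
#' @export
#' @examples
#' fit_power_law(1:10, 2 * (1:10) + 3)  # a=2, n=1, b=3
fit_power_law <- function(x, y = NULL, fit_range = NULL) {
  if (inherits(x, "threshold_curve")) {
    y <- x$threshold
    x <- x$background
  }
  keep <- is.finite(x) & is.finite(y)
  if (!is.null(fit_range)) keep <- keep & x >= fit_range[1L] & x <= fit_range[2L]
  x <- x[keep]; y <- y[keep]
  if (length(x) < 4L) stop("need at least 4 points in the fit range")
  a0 <- (y[length(y)] - y[1L]) / (x[length(x)] - x[1L])
  if (!is.finite(a0) || a0 == 0) a0 <- 1
  start <- list(a = a0, n = 1, b = y[1L])
  dat <- data.frame(x = x, y = y)
  fit <- NULL
  for (attempt in 1:6) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a * x^n + b, data = dat, start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit)) break
    start <- list(a = a0 * stats::runif(1, 0.2, 5),
                  n = stats::runif(1, 0.3, 2),
                  b = y[1L] * stats::runif(1, 0.5, 1.5))
  }
  if (is.null(fit)) stop("power-law fit did not converge after restarts")
  cf <- summary(fit)$coefficients
  resid <- stats::resid(fit)
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  structure(list(a = cf["a", 1L], n = cf["n", 1L], b = cf["b", 1L],
                 se_a = cf["a", 2L], se_n = cf["n", 2L], se_b = cf["b", 2L],
                 r2 = r2, range = range(x), n_points = length(x)),
            class = "law_fit")
}

#' @export
print.law_fit <- function(x, ...) {
  cat("<law_fit> threshold = a * background^n + b\n")
  cat(sprintf("  a = %.5g (se %.2g), n = %.5g (se %.2g), b = %.5g (se %.2g)\n",
              x$a, x$se_a, x$n, x$se_n, x$b, x$se_b))
  cat(sprintf("  R^2 = %.6f over background range [%g, %g] (%d points)\n",
              x$r2, x$range[1L], x$range[2L], x$n_points))
  invisible(x)
}

#' Ordinary least-squares linearity diagnostics
#'
#' Slope, intercept and coefficient of determination of `y` on `x`, used to
#' check the Weber-law linearity of threshold and perception curves.
#'
#' @param x,y Numeric vectors (at least 3 points; `x` must vary).
#' @return List with `slope`, `intercept`, `r2`.
#' @export
linearity_diagnostics <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 points")
  if (stats::var(x) == 0) stop("degenerate x: zero variance")
  fit <- stats::lm(y ~ x)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(stats::resid(fit)^2) / sst
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r2 = r2)
}
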