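# Piecewise-constant perturbation protocols, stiff integration and the
# response metrics (maximum excursion, time-to-peak, resetting period).

.DEFAULT_RTOL <- 1e-8
.DEFAULT_ATOL <- 1e-10
.WINDUP_GUARD <- 1e12

#' Define a piecewise-constant perturbation protocol
#'
#' A protocol is an ordered list of phases; each phase starts at a given time
#' and holds a set of parameter overrides constant until the next phase
#' begins.  Integration is restarted exactly at every phase boundary, so
#' short pulses (e.g. 10 ms) are not smeared by the step-size control.
#'
#' @param phases List of phases, each a list with elements `start` (time) and
#'   `overrides` (named list of parameter values).  The first phase must
#'   start at 0 and start times must be strictly increasing.
#' @param total_time End of the simulated window.
#' @param dense_output_step Output grid spacing.
#' @return An object of class `perturbation_protocol`.
#' @export
#' @examples
#' perturbation_protocol(
#'   list(list(start = 0, overrides = list()),
#'        list(start = 10, overrides = list(k2 = 5))),
#'   total_time = 60)
perturbation_protocol <- function(phases, total_time,
                                  dense_output_step = 0.01) {
  if (!is.list(phases) || !length(phases)) stop("'phases' must be a non-empty list")
  starts <- vapply(phases, function(ph) as.numeric(ph$start), numeric(1))
  if (starts[1L] != 0) stop("first phase must start at time 0")
  if (any(diff(starts) <= 0)) stop("phase start times must be strictly increasing")
  if (total_time <= starts[length(starts)]) {
    stop("'total_time' must exceed the last phase start")
  }
  if (dense_output_step <= 0) stop("'dense_output_step' must be > 0")
  phases <- lapply(phases, function(ph) {
    ov <- ph$overrides
    if (is.null(ov)) ov <- list()
    list(start = as.numeric(ph$start), overrides = ov)
  })
  structure(list(phases = phases, total_time = total_time,
                 dense_output_step = dense_output_step),
            class = "perturbation_protocol")
}

#' Convenience constructors for common protocols
#'
#' `step_protocol()` holds baseline parameters, then applies `overrides` from
#' `onset` to the end of the window; `pulse_protocol()` applies them for
#' `width` time units only.
#'
#' @param onset Time at which the step/pulse is applied.
#' @param overrides Named list of parameter values for the step/pulse phase.
#' @param total_time End of the simulated window.
#' @param width Pulse duration.
#' @param baseline Named list applied during all phases (e.g. a background).
#' @param dense_output_step Output grid spacing.
#' @return A `perturbation_protocol`.
#' @export
step_protocol <- function(onset, overrides, total_time,
                          baseline = list(), dense_output_step = 0.01) {
  on_phase <- list(start = onset,
                   overrides = utils::modifyList(baseline, overrides))
  phases <- if (onset == 0) list(on_phase)
            else list(list(start = 0, overrides = baseline), on_phase)
  perturbation_protocol(phases, total_time = total_time,
                        dense_output_step = dense_output_step)
}

#' @rdname step_protocol
#' @export
pulse_protocol <- function(onset, overrides, width, total_time,
                           baseline = list(), dense_output_step = 0.01) {
  on_phase <- list(start = onset,
                   overrides = utils::modifyList(baseline, overrides))
  off_phase <- list(start = onset + width, overrides = baseline)
  phases <- if (onset == 0) list(on_phase, off_phase)
            else list(list(start = 0, overrides = baseline), on_phase,
                      off_phase)
  perturbation_protocol(phases, total_time = total_time,
                        dense_output_step = dense_output_step)
}

.windup_error <- function(msg, phase = NA_integer_) {
  stop(structure(class = c("homeostat_windup", "error", "condition"),
                 list(message = msg, call = sys.call(-1), phase = phase)))
}

#' Simulate a model under a perturbation protocol
#'
#' Integrates the model's ODEs with a stiff-capable solver (LSODA), phase by
#' phase, restarting exactly at each phase boundary.  Divergence beyond an
#' overflow guard is reported as integral windup (condition class
#' `homeostat_windup`).
#'
#' @param model A `controller_model`.
#' @param protocol A `perturbation_protocol`.  Override names must be
#'   existing model parameters.
#' @param initial_state Starting state; defaults to the steady state under
#'   the first phase's parameters.
#' @param rtol,atol Solver tolerances.
#' @return A `trajectory`: a data frame with column `time` and one column per
#'   state variable, carrying the model and protocol as attributes.
#' @export
simulate_model <- function(model, protocol, initial_state = NULL,
                           rtol = .DEFAULT_RTOL, atol = .DEFAULT_ATOL) {
  stopifnot(inherits(model, "controller_model"),
            inherits(protocol, "perturbation_protocol"))
  for (ph in protocol$phases) .merge_overrides(model$pars, ph$overrides)

  if (is.null(initial_state)) {
    initial_state <- find_steady_state(model,
                                       overrides = protocol$phases[[1L]]$overrides)
  }
  y <- stats::setNames(unlist(initial_state), model$state_names)
  if (any(!is.finite(y)) || any(y < 0)) {
    stop("initial state must be finite and >= 0")
  }

  starts <- vapply(protocol$phases, `[[`, numeric(1), "start")
  ends <- c(starts[-1L], protocol$total_time)
  h <- protocol$dense_output_step
  out_list <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    p <- .merge_overrides(model$pars, protocol$phases[[i]]$overrides)
    tt <- seq(starts[i], ends[i], by = h)
    if (tt[length(tt)] < ends[i]) tt <- c(tt, ends[i])
    sol <- deSolve::lsoda(y, tt, model$rhs, p, rtol = rtol, atol = atol)
    m <- unclass(sol)
    if (any(!is.finite(m))) {
      .windup_error(paste0("integration diverged in phase ", i,
                           " (non-finite state): integral windup or solver failure"),
                    phase = i)
    }
    if (max(m[, -1L, drop = FALSE]) > .WINDUP_GUARD) {
      .windup_error(paste0("state exceeded overflow guard in phase ", i,
                           ": integral windup"), phase = i)
    }
    if (nrow(m) < length(tt)) {
      stop("solver failed in phase ", i, " at t = ", m[nrow(m), 1L])
    }
    y <- stats::setNames(m[nrow(m), -1L], model$state_names)
    out_list[[i]] <- if (i == 1L) m else m[-1L, , drop = FALSE]
  }
  out <- do.call(rbind, out_list)
  traj <- as.data.frame(out)
  names(traj) <- c("time", model$state_names)
  attr(traj, "model") <- model
  attr(traj, "protocol") <- protocol
  class(traj) <- c("trajectory", "data.frame")
  traj
}

#' Find a model's steady state
#'
#' For the basic motifs the closed form is used and verified against the rate
#' field; for the photoreceptor model the steady state is reduced to a scalar
#' root in cytosolic calcium (the K-balance pins the pump flux at `k6`).  If
#' no steady state exists because the compensatory mechanism cannot balance
#' the load, an error of condition class `homeostat_windup` is signalled,
#' distinct from numerical failure.
#'
#' @param model A `controller_model`.
#' @param overrides Named parameter overrides.
#' @param guess Positive starting state for the integration fallback.
#' @param tol Maximum absolute rate residual accepted, per component.
#' @return Named numeric steady-state vector.
#' @export
find_steady_state <- function(model, overrides = NULL, guess = NULL,
                              tol = 1e-9) {
  stopifnot(inherits(model, "controller_model"))
  if (model$kind == "photoreceptor") {
    ss <- .photo_steady_state(.merge_overrides(model$pars, overrides),
                              loop3_on = model$loops[["loop3"]])
    return(ss)
  }
  ss <- tryCatch(analytic_steady_state(model, overrides = overrides),
                 error = function(e) e)
  if (!inherits(ss, "error")) {
    res <- rate_field(model, ss, overrides)
    if (max(abs(res)) < max(tol, 1e-6 * max(abs(ss)))) return(ss)
  } else if (grepl("no positive", conditionMessage(ss))) {
    .windup_error(conditionMessage(ss))
  }
  # fallback: relax by integration, then verify stability
  p <- .merge_overrides(model$pars, overrides)
  y <- if (is.null(guess)) {
    stats::setNames(rep(1, length(model$state_names)), model$state_names)
  } else stats::setNames(unlist(guess), model$state_names)
  t_chunk <- 100
  for (i in 1:20) {
    sol <- deSolve::lsoda(y, c(0, t_chunk), model$rhs, p,
                          rtol = .DEFAULT_RTOL, atol = .DEFAULT_ATOL)
    ynew <- stats::setNames(sol[nrow(sol), -1L], model$state_names)
    if (any(!is.finite(ynew)) || max(ynew) > .WINDUP_GUARD) {
      .windup_error("state diverged during relaxation: integral windup")
    }
    y <- ynew
    if (max(abs(model$rhs(0, y, p)[[1L]])) < tol) break
    t_chunk <- t_chunk * 2
  }
  res <- abs(model$rhs(0, y, p)[[1L]])
  if (max(res) >= tol) {
    stop("no steady state found: residual ", signif(max(res), 3),
         " after relaxation")
  }
  y
}

# quadratic (three-point) refinement of a grid extremum
.refine_extremum <- function(tt, xx, i) {
  n <- length(xx)
  if (i <= 1L || i >= n) return(list(t = tt[i], x = xx[i]))
  y1 <- xx[i - 1L]; y2 <- xx[i]; y3 <- xx[i + 1L]
  denom <- y1 - 2 * y2 + y3
  if (denom == 0) return(list(t = tt[i], x = xx[i]))
  delta <- 0.5 * (y1 - y3) / denom
  h <- tt[i + 1L] - tt[i]
  list(t = tt[i] + delta * h, x = y2 - (y1 - y3)^2 / (8 * denom))
}

#' Response metrics of a perturbation response
#'
#' Extracts, for the controlled variable, the maximum absolute excursion from
#' the reference level after perturbation onset (`delta_max`, with quadratic
#' refinement of the grid extremum), the time from onset to that extremum
#' (`t_max`, earliest maximum on ties), and the resetting period: the first
#' time after which the variable stays within `band_fraction * reference` of
#' the reference for the remainder of the simulated window.
#'
#' @param traj A `trajectory`.
#' @param reference_level Reference level of the controlled variable
#'   (set-point for the basic motifs; pre-perturbation steady state for the
#'   photoreceptor model).
#' @param onset_time Perturbation onset; metrics are measured from here.
#' @param band_fraction Half-width of the resetting band, as a fraction of
#'   the reference level (default 1%, the just-noticeable-difference
#'   convention).
#' @param variable Which state column to analyse (default: the model's
#'   controlled variable, else the first state column).
#' @return A list of class `response_metrics`: `delta_max`, `t_max`,
#'   `resetting_time`, `direction` (`"below"`/`"above"`), and
#'   `resetting_resolved` (FALSE if the band is never re-entered for good;
#'   in that case `resetting_time` is NA rather than silently truncated).
#' @export
response_metrics <- function(traj, reference_level, onset_time = 0,
                             band_fraction = 0.01, variable = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  model <- attr(traj, "model")
  if (is.null(variable)) {
    variable <- if (!is.null(model)) model$controlled else names(traj)[2L]
  }
  tt <- traj$time
  if (onset_time < tt[1L] || onset_time > tt[length(tt)]) {
    stop("onset_time outside the trajectory window")
  }
  sel <- tt >= onset_time
  tt <- tt[sel]
  xx <- traj[[variable]][sel]
  dev <- xx - reference_level

  i <- which.max(abs(dev))
  ref <- .refine_extremum(tt, dev, i)
  delta_max <- abs(ref$x)
  t_max <- ref$t - onset_time
  direction <- if (ref$x < 0) "below" else "above"

  band <- band_fraction * abs(reference_level)
  outside <- abs(dev) > band
  if (!any(outside)) {
    resetting <- 0
    resolved <- TRUE
  } else {
    last_out <- max(which(outside))
    if (last_out == length(dev)) {
      resetting <- NA_real_
      resolved <- FALSE
    } else {
      resetting <- tt[last_out + 1L] - onset_time
      resolved <- TRUE
    }
  }
  structure(list(delta_max = delta_max, t_max = max(t_max, 0),
                 resetting_time = resetting, direction = direction,
                 resetting_resolved = resolved,
                 reference_level = reference_level, variable = variable),
            class = "response_metrics")
}

#' @export
print.response_metrics <- function(x, ...) {
  cat("<response_metrics> ", x$variable, " vs reference ",
      format(x$reference_level), "\n", sep = "")
  cat("  delta_max =", format(x$delta_max),
      " (", x$direction, "),  t_max =", format(x$t_max), "\n")
  cat("  resetting_time =",
      if (x$resetting_resolved) format(x$resetting_time) else "unresolved", "\n")
  invisible(x)
}

#' Sweep a parameter and tabulate response metrics
#'
#' Re-runs a protocol for each value of a swept parameter and collects the
#' response metrics.  The sweep value is applied either to every phase
#' (`phase = NULL`, e.g. a background sweep) or to selected phases (e.g.
#' `phase = 2` for a step-size sweep).  The reference level is the motif's
#' set-point, or the pre-perturbation steady state for models without an
#' exact set-point.  Per-value failures are recorded (NA row) and the sweep
#' continues.
#'
#' @param model A `controller_model`.
#' @param protocol Template `perturbation_protocol`.
#' @param parameter Name of the swept parameter.
#' @param values Numeric values to sweep over.
#' @param phase `NULL` (all phases) or integer indices of phases receiving
#'   the swept value.
#' @param onset_time Perturbation onset used for the metrics (default: start
#'   of the second phase, or 0 for single-phase protocols).
#' @param band_fraction Resetting band (see [response_metrics()]).
#' @return A data frame: `sweep_value`, `delta_max`, `t_max`,
#'   `resetting_time`, `error`.
#' @export
sweep_metrics <- function(model, protocol, parameter, values, phase = NULL,
                          onset_time = NULL, band_fraction = 0.01) {
  stopifnot(inherits(model, "controller_model"),
            inherits(protocol, "perturbation_protocol"))
  if (any(!is.finite(values))) stop("sweep values must be finite")
  if (is.null(onset_time)) {
    onset_time <- if (length(protocol$phases) > 1L)
      protocol$phases[[2L]]$start else 0
  }
  rows <- lapply(values, function(v) {
    prot <- protocol
    idx <- if (is.null(phase)) seq_along(prot$phases) else phase
    for (i in idx) {
      prot$phases[[i]]$overrides[[parameter]] <- v
    }
    tryCatch({
      y0 <- find_steady_state(model, overrides = prot$phases[[1L]]$overrides)
      ref <- if (model$kind == "motif") model$set_point
             else y0[[model$controlled]]
      traj <- simulate_model(model, prot, initial_state = y0)
      met <- response_metrics(traj, ref, onset_time = onset_time,
                              band_fraction = band_fraction)
      data.frame(sweep_value = v, delta_max = met$delta_max,
                 t_max = met$t_max, resetting_time = met$resetting_time,
                 error = NA_character_)
    }, error = function(e) {
      data.frame(sweep_value = v, delta_max = NA_real_, t_max = NA_real_,
                 resetting_time = NA_real_, error = conditionMessage(e))
    })
  })
  do.call(rbind, rows)
}

#' Write a trajectory (or metrics table) to CSV with a JSON sidecar
#'
#' The CSV holds `time` plus one column per state variable at full double
#' precision; the sidecar records the protocol and model parameters.
#'
#' @param traj A `trajectory`.
#' @param path CSV output path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  model <- attr(traj, "model")
  protocol <- attr(traj, "protocol")
  side <- list(
    model = list(kind = model$kind,
                 motif_id = if (!is.null(model$motif_id)) model$motif_id,
                 integral_mode = model$integral_mode,
                 parameters = as.list(model$pars)),
    protocol = list(phases = protocol$phases,
                    total_time = protocol$total_time,
                    dense_output_step = protocol$dense_output_step))
  jsonlite::write_json(side, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
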