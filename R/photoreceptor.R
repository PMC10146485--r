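# Three-feedback-loop kinetic model of vertebrate photoreceptor adaptation.
#
# State: cGMP (uM), cytosolic Ca (uM) and K (uM).  cGMP is synthesized by
# guanylate cyclase (GC, inhibited by Ca -- feedback loop 1), hydrolysed
# constitutively (k9) and by light-activated, Ca-activated PDE (k2 step +
# k4 background -- feedback loop 2).  cGMP opens CNG channels letting Ca in;
# Ca inhibits the CNG channel (feedback loop 3).  NCKX extrudes Ca together
# with K in a bimolecular reaction (k7*Ca*K), which -- with the constant K
# inflow k6 -- realizes antithetic integral control of cGMP whenever loop 3
# is absent.  A constant (zero-order) leak vleak feeds Ca from internal
# stores into the cytosol.

.PHOTO_DEFAULTS <- c(
  k1 = 0,        # uM/s  cGMP inflow perturbation
  k2 = 1,        # 1/s   light perturbation (stepped/pulsed)
  k3 = 50,       # uM/s  maximal GC rate
  k4 = 0,        # 1/s   light background
  k5 = 100,      # uM/s  maximal CNG-mediated Ca inflow
  k6 = 0.5,      # uM/s  constant K inflow
  k7 = 2.0,      # 1/(uM s) NCKX bimolecular constant
  k8 = 0.05749,  # uM    GC inhibition constant (57.49 nM)
  k9 = 1.0,      # 1/s   dark cGMP hydrolysis
  k10 = 0.06357, # uM    CNG Ca-inhibition constant (63.57 nM)
  k11 = 32.81,   # uM    CNG cGMP-activation constant
  k12 = 0.622612,# uM    PDE Ca-activation constant (622.612 nM)
  r = 1.65,      # GC inhibition Hill exponent
  p = 0.894,     # PDE activation Hill exponent
  n = 4.14,      # CNG cGMP-activation Hill exponent
  m = 2.50,      # CNG Ca-inhibition Hill exponent
  alpha = 0.6067,      # Ca-sensitive CNG amplitude
  beta_prime = 0.4007, # Ca-insensitive CNG amplitude
  vleak = NA           # uM/s  constant Ca leak (calibrated by default)
)

# printed reference steady states used for leak calibration and
# self-consistency tests (concentrations in uM)
.PHOTO_REFERENCE_STATES <- list(
  fig19a = list(cGMP = 7.612, Ca = 0.1417, loops = c(TRUE, TRUE, FALSE)),
  fig19d = list(cGMP = 9.042, Ca = 0.1257, loops = c(TRUE, TRUE, TRUE)),
  fig15_dark = list(cGMP = 9.04191, Ca = 0.125717, loops = c(TRUE, TRUE, TRUE))
)

.hill_up <- function(x, K, h) {
  if (K <= 0) return(rep_len(1, length(x)))
  xh <- x^h
  xh / (K^h + xh)
}
.hill_down <- function(x, K, h) {
  Kh <- K^h
  Kh / (Kh + x^h)
}

.cng_ca_term <- function(Ca, p, loop3_on) {
  if (!loop3_on) return(rep_len(1, length(Ca)))
  p[["alpha"]] * .hill_down(Ca, p[["k10"]], p[["m"]]) + p[["beta_prime"]]
}

.photo_rhs_factory <- function(loop3_on) {
  force(loop3_on)
  function(t, y, p) {
    cG <- y[[1L]]; Ca <- y[[2L]]; K <- y[[3L]]
    pump <- p[["k7"]] * Ca * K
    list(c(
      p[["k1"]] + p[["k3"]] * .hill_down(Ca, p[["k8"]], p[["r"]]) -
        p[["k9"]] * cG -
        (p[["k2"]] + p[["k4"]]) * cG * .hill_up(Ca, p[["k12"]], p[["p"]]),
      p[["k5"]] * .hill_up(cG, p[["k11"]], p[["n"]]) *
        .cng_ca_term(Ca, p, loop3_on) - pump + p[["vleak"]],
      p[["k6"]] - pump
    ))
  }
}

#' Photoreceptor model parameters
#'
#' The default constants of the phototransduction model: GC/PDE/CNG Hill
#' parameters fitted to normalized dose-response data, NCKX and K-inflow
#' constants, dark hydrolysis rate and the constant calcium leak.
#' Concentrations are in micromolar, time in seconds.
#'
#' @param ... Named overrides of the defaults (e.g. `k4 = 10`).
#' @return Named numeric vector of parameters.  `vleak` is `NA` here; it is
#'   filled in (by calibration or explicitly) when building the model with
#'   [photo_model()].
#' @export
photo_parameters <- function(...) {
  ov <- c(...)
  p <- .PHOTO_DEFAULTS
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("unknown photoreceptor parameters: ",
                          paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  p
}

#' Apply feedback-loop toggles to photoreceptor parameters
#'
#' Disabling conventions: loop 1 (Ca inhibition of GC) is removed by setting
#' the inhibition constant `k8 = 1e9` uM with `r = 1`; loop 2 (Ca activation
#' of light-induced PDE) by `k12 = 0`, which saturates the activation factor
#' at 1; loop 3 (Ca inhibition of the CNG channel) by replacing the CNG
#' Ca-modifier with the constant 1 (its low-calcium limit).  Other constants
#' are untouched.  At least one of loops 1-2 must stay on, otherwise no
#' feedback acts on cGMP.
#'
#' @param params Parameter vector from [photo_parameters()].
#' @param loop1_on,loop2_on,loop3_on Logical toggles.
#' @return The modified parameter vector, with a `loops` attribute.
#' @export
loop_config <- function(params, loop1_on = TRUE, loop2_on = TRUE,
                        loop3_on = TRUE) {
  if (!loop1_on && !loop2_on) {
    stop("at least one of feedback loops 1 and 2 must be on: ",
         "otherwise no feedback acts on cGMP")
  }
  if (!loop1_on) {
    params[["k8"]] <- 1e9
    params[["r"]] <- 1
  }
  if (!loop2_on) params[["k12"]] <- 0
  attr(params, "loops") <- c(loop1 = loop1_on, loop2 = loop2_on,
                             loop3 = loop3_on)
  params
}

#' Calibrate the constant calcium leak from a reference steady state
#'
#' At any steady state the K-balance pins the NCKX pump flux at exactly
#' `k6`, so the calcium balance gives
#' `vleak = k6 - k5 * h(cGMP) * z(Ca)`, where `h` is the CNG cGMP-activation
#' Hill function and `z` the CNG Ca-inhibition term (identically 1 when
#' loop 3 is off).
#'
#' @param params Parameter vector from [photo_parameters()].
#' @param reference_state List/vector with elements `cGMP` and `Ca` (uM) of
#'   a printed steady state.
#' @param loop3_on Whether loop 3 was active in the reference configuration.
#' @return The leak rate `vleak` in uM/s.
#' @export
#' @examples
#' calibrate_leak(photo_parameters(),
#'                list(cGMP = 7.612, Ca = 0.1417), loop3_on = FALSE)
calibrate_leak <- function(params, reference_state, loop3_on = FALSE) {
  cG <- reference_state[["cGMP"]]
  Ca <- reference_state[["Ca"]]
  stopifnot(is.finite(cG), is.finite(Ca), cG >= 0, Ca >= 0)
  vleak <- params[["k6"]] -
    params[["k5"]] * .hill_up(cG, params[["k11"]], params[["n"]]) *
    .cng_ca_term(Ca, params, loop3_on)
  if (vleak < -1e-12) {
    stop("calibration gives a negative leak rate (", signif(vleak, 4),
         " uM/s): the reference state is inconsistent with the parameters")
  }
  max(vleak, 0)
}

#' Build the photoreceptor model
#'
#' Assembles the three-state phototransduction model as a simulable
#' `controller_model`.  By default the calcium leak `vleak` is calibrated
#' from the bundled reference steady state of the antagonistic loops-1+2
#' configuration (cGMP = 7.612 uM, Ca = 141.7 nM), making the calibration
#' auditable via [calibrate_leak()].
#'
#' @param params Parameter vector from [photo_parameters()].
#' @param vleak Calcium leak (uM/s); `NULL` (default) calibrates it from the
#'   bundled reference state.  Must stay below the K inflow `k6`, otherwise
#'   the NCKX pump cannot absorb the leak and cytosolic calcium winds up.
#' @param loop1_on,loop2_on,loop3_on Feedback-loop toggles (see
#'   [loop_config()]).
#' @return An object of class `c("photo_model", "controller_model")`.
#' @export
#' @examples
#' ph <- photo_model()
#' find_steady_state(ph)  # dark-adapted steady state
photo_model <- function(params = photo_parameters(), vleak = NULL,
                        loop1_on = TRUE, loop2_on = TRUE, loop3_on = TRUE) {
  if (is.null(vleak)) {
    if (is.na(params[["vleak"]])) {
      ref <- .PHOTO_REFERENCE_STATES$fig19a
      vleak <- calibrate_leak(params, ref, loop3_on = ref$loops[3L])
    } else {
      vleak <- params[["vleak"]]
    }
  }
  if (!is.finite(vleak) || vleak < 0) stop("'vleak' must be finite and >= 0")
  params[["vleak"]] <- vleak
  params <- loop_config(params, loop1_on, loop2_on, loop3_on)
  loops <- attr(params, "loops")
  attr(params, "loops") <- NULL
  sumab <- params[["alpha"]] + params[["beta_prime"]]
  if (loop3_on && (sumab < 0.99 || sumab > 1.02)) {
    warning("alpha + beta_prime = ", signif(sumab, 4),
            " is away from 1; the low-calcium CNG limit will not approach ",
            "the loop-3-off convention")
  }
  set_point <- if (!loop3_on) {
    tryCatch(cgmp_set_point(params), error = function(e) NA_real_)
  } else NA_real_
  structure(
    list(kind = "photoreceptor",
         integral_mode = "antithetic",
         pars = params,
         loops = loops,
         flow_class = NA_character_,
         compensation = "derepression",
         state_names = c("cGMP", "Ca", "K"),
         controlled = "cGMP",
         set_point = set_point,
         perturbation_name = "k2",
         background_name = "k4",
         rhs = .photo_rhs_factory(loop3_on)),
    class = c("photo_model", "controller_model"))
}

#' @export
print.photo_model <- function(x, ...) {
  on <- names(x$loops)[x$loops]
  cat("<photo_model> feedback loops on:",
      if (length(on)) paste(on, collapse = ", ") else "none", "\n")
  cat("  vleak =", format(x$pars[["vleak"]]), "uM/s")
  if (!is.na(x$set_point)) cat(",  cGMP set-point =", format(x$set_point), "uM")
  cat("\n")
  invisible(x)
}

#' Evaluate the photoreceptor rate field
#'
#' @param state Numeric vector `(cGMP, Ca, K)` in uM.
#' @param params Full parameter vector including `vleak`.
#' @param light_overrides Named overrides (e.g. `c(k2 = 50)`).
#' @param loop3_on Whether the CNG Ca-inhibition term is active.
#' @return Named derivative vector.
#' @export
photo_rate_field <- function(state, params, light_overrides = NULL,
                             loop3_on = TRUE) {
  state <- unlist(state)
  if (length(state) != 3L) stop("state must be (cGMP, Ca, K)")
  if (any(!is.finite(state)) || any(state < 0)) {
    stop("state entries must be finite and >= 0")
  }
  if (!is.null(light_overrides)) {
    ov <- unlist(light_overrides)
    bad <- setdiff(names(ov), names(params))
    if (length(bad)) stop("overrides name unknown parameters: ",
                          paste(bad, collapse = ", "))
    params[names(ov)] <- ov
  }
  d <- .photo_rhs_factory(loop3_on)(0, state, params)[[1L]]
  stats::setNames(d, c("cGMP", "Ca", "K"))
}

#' Closed-form cGMP set-point of the antagonistic loops-1+2 configuration
#'
#' With loop 3 off, the NCKX term realizes antithetic integral control of
#' cGMP and the defended steady state has the closed form
#' `cGMP_set = k11 * (b / (1 - b))^(1/n)` with `b = (k6 - vleak) / k5`.
#'
#' @param params Full parameter vector including `vleak` (or a
#'   `photo_model`, whose parameters are used).
#' @return The set-point in uM.
#' @export
#' @examples
#' ph <- photo_model(loop3_on = FALSE)
#' cgmp_set_point(ph)  # ~7.61 uM
cgmp_set_point <- function(params) {
  if (inherits(params, "controller_model")) params <- params$pars
  vleak <- params[["vleak"]]
  if (is.na(vleak)) stop("'vleak' has not been set; build the model first")
  b <- (params[["k6"]] - vleak) / params[["k5"]]
  if (b < 0) {
    .windup_error("no set-point: leak exceeds the K inflow k6 (windup regime)")
  }
  if (b >= 1) stop("no set-point: (k6 - vleak)/k5 must be < 1")
  if (b == 0) return(0)
  params[["k11"]] * (b / (1 - b))^(1 / params[["n"]])
}

# steady state reduced to a scalar root in Ca: the K-balance forces
# pump = k6, and the cGMP balance gives cGMP as a function of Ca
.photo_steady_state <- function(p, loop3_on) {
  cg_of_ca <- function(Ca) {
    (p[["k1"]] + p[["k3"]] * .hill_down(Ca, p[["k8"]], p[["r"]])) /
      (p[["k9"]] + (p[["k2"]] + p[["k4"]]) * .hill_up(Ca, p[["k12"]], p[["p"]]))
  }
  fres <- function(Ca) {
    p[["k5"]] * .hill_up(cg_of_ca(Ca), p[["k11"]], p[["n"]]) *
      .cng_ca_term(Ca, p, loop3_on) - p[["k6"]] + p[["vleak"]]
  }
  lo <- 1e-9; hi <- 1e3
  flo <- fres(lo); fhi <- fres(hi)
  if (flo > 0 && fhi > 0) {
    .windup_error(paste0("no steady state: CNG calcium inflow plus leak ",
                         "always exceeds the NCKX removal capacity k6 = ",
                         p[["k6"]], "; cytosolic calcium winds up"))
  }
  if (flo < 0 && fhi < 0) {
    .windup_error("no steady state: CNG calcium inflow plus leak stays below \
the constant K inflow k6; the K pool winds up")
  }
  Ca <- stats::uniroot(fres, c(lo, hi), f.lower = flo, f.upper = fhi,
                       tol = 1e-15)$root
  cG <- cg_of_ca(Ca)
  c(cGMP = cG, Ca = Ca, K = p[["k6"]] / (p[["k7"]] * Ca))
}

#' Apply a light pulse to the photoreceptor model
#'
#' Pre-equilibrates (dark-adapts) the model at the baseline light level under
#' the given background, then raises the light perturbation `k2` to
#' `pulse_height` for exactly `pulse_width` seconds and follows the
#' relaxation.  The reported excursion is the maximum downward deviation of
#' cGMP from its pre-pulse steady state.
#'
#' @param model A `photo_model`.
#' @param pulse_height Pulse value of `k2` (1/s).
#' @param pulse_width Pulse duration in seconds (default 10 ms).
#' @param background Constant background `k4` (1/s).
#' @param horizon Simulated window after pulse onset (s).
#' @param dense_output_step Output grid spacing (s).
#' @return List with `trajectory`, `delta_cgmp`, `metrics` and
#'   `pre_pulse_state`.
#' @export
run_pulse <- function(model, pulse_height, pulse_width = 0.01,
                      background = 0, horizon = 6,
                      dense_output_step = 0.002) {
  stopifnot(inherits(model, "photo_model"))
  base <- list(k4 = background)
  y0 <- find_steady_state(model, overrides = base)
  prot <- pulse_protocol(onset = 0, overrides = list(k2 = pulse_height),
                         width = pulse_width, total_time = horizon,
                         baseline = base,
                         dense_output_step = dense_output_step)
  traj <- simulate_model(model, prot, initial_state = y0)
  met <- response_metrics(traj, y0[["cGMP"]], onset_time = 0)
  list(trajectory = traj, delta_cgmp = met$delta_max, metrics = met,
       pre_pulse_state = y0)
}

#' Apply a light step to the photoreceptor model
#'
#' Pre-equilibrates at the baseline light level under the given background
#' (or starts from `initial_state` if supplied), then steps `k2` to
#' `step_height`; optionally the step is switched off after `off_at`
#' seconds, restoring the baseline.
#'
#' @param model A `photo_model`.
#' @param step_height Step value of `k2` (1/s).
#' @param background Constant background `k4` (1/s).
#' @param duration Simulated window (s).
#' @param off_at Optional step-off time (s).
#' @param initial_state Optional starting state (uM); default: the steady
#'   state at baseline.  The reference level for the metrics is the initial
#'   cGMP level.
#' @param dense_output_step Output grid spacing (s).
#' @return List with `trajectory`, `metrics` and `pre_step_state`.
#' @export
run_step <- function(model, step_height, background = 0, duration = 3,
                     off_at = NULL, initial_state = NULL,
                     dense_output_step = 0.001) {
  stopifnot(inherits(model, "photo_model"))
  base <- list(k4 = background)
  y0 <- if (is.null(initial_state)) find_steady_state(model, overrides = base)
        else stats::setNames(unlist(initial_state), model$state_names)
  prot <- if (is.null(off_at)) {
    perturbation_protocol(
      list(list(start = 0, overrides = utils::modifyList(base, list(k2 = step_height)))),
      total_time = duration, dense_output_step = dense_output_step)
  } else {
    pulse_protocol(onset = 0, overrides = list(k2 = step_height),
                   width = off_at, total_time = duration, baseline = base,
                   dense_output_step = dense_output_step)
  }
  traj <- simulate_model(model, prot, initial_state = y0)
  met <- response_metrics(traj, y0[["cGMP"]], onset_time = 0)
  list(trajectory = traj, metrics = met, pre_step_state = y0)
}

#' Pulse-threshold curve of the photoreceptor model
#'
#' For each background, finds the 10 ms pulse height of `k2` whose maximum
#' downward cGMP excursion equals `target` (default 0.03 uM, i.e. about 1%
#' of the dark cGMP level), via the bracketed root search of
#' [threshold_stimulus()].  The pre-pulse steady-state calcium level is
#' recorded as the background-dependent operating point.
#'
#' @param model A `photo_model`.
#' @param backgrounds Sorted background values `k4` (1/s).
#' @param target Target cGMP excursion (uM).
#' @param pulse_width Pulse duration (s).
#' @param ... Passed to [threshold_stimulus()].
#' @return A data frame of class `threshold_curve`: `background`,
#'   `threshold`, `Ca_ss`, `inv_Ca_ss`, `error`.
#' @export
photo_threshold_curve <- function(model, backgrounds, target = 0.03,
                                  pulse_width = 0.01, ...) {
  stopifnot(inherits(model, "photo_model"))
  if (is.unsorted(backgrounds)) stop("'backgrounds' must be sorted increasingly")
  rows <- lapply(backgrounds, function(bg) {
    tryCatch({
      thr <- threshold_stimulus(model, background = bg,
                                target_excursion = target,
                                stimulus_kind = "pulse",
                                pulse_width = pulse_width, ...)
      ss <- find_steady_state(model, overrides = list(k4 = bg))
      data.frame(background = bg, threshold = thr, Ca_ss = ss[["Ca"]],
                 inv_Ca_ss = 1 / ss[["Ca"]], error = NA_character_)
    }, error = function(e) {
      data.frame(background = bg, threshold = NA_real_, Ca_ss = NA_real_,
                 inv_Ca_ss = NA_real_, error = conditionMessage(e))
    })
  })
  out <- do.call(rbind, rows)
  attr(out, "target_excursion") <- target
  attr(out, "stimulus_kind") <- "pulse"
  class(out) <- c("threshold_curve", "data.frame")
  out
}

#' Feedback-loop dissection scenarios
#'
#' Reproduces the three-phase inflow/outflow perturbation experiment on the
#' photoreceptor model under four feedback configurations:
#' * `"a"` -- antagonistic loops 1+2 (loop 3 off): robust perfect adaptation
#'   of cGMP at its closed-form set-point in all three phases;
#' * `"b"` -- loop 2 only; the background `k4` must be raised (default 8/s)
#'   so the PDE can supply the compensatory outflow, otherwise calcium winds
#'   up;
#' * `"c"` -- loop 1 only; the maximal GC rate `k3` is raised to 500 uM/s in
#'   phase 3 so the compensatory inflow can match the outflow perturbation;
#' * `"d"` -- all three loops: perfect adaptation is lost but cGMP and Ca
#'   vary only little.
#'
#' The phase profile is: phase 1 `k1 = 0, k2 = 1/s`; phase 2
#' `k1 = 7 uM/s, k2 = 0`; phase 3 `k1 = 0, k2 = 7/s`.
#'
#' @param scenario One of `"a"`, `"b"`, `"c"`, `"d"`.
#' @param params Parameter vector from [photo_parameters()].
#' @param phase_duration Duration of each phase (s).
#' @param scenario_b_background Background `k4` for scenario `"b"` (1/s).
#' @param dense_output_step Output grid spacing (s).
#' @return A `trajectory`; its `"model"` attribute carries the configured
#'   model (including the set-point where one exists).
#' @export
feedback_scenario <- function(scenario = c("a", "b", "c", "d"),
                              params = photo_parameters(),
                              phase_duration = 100,
                              scenario_b_background = 8,
                              dense_output_step = 0.01) {
  scenario <- match.arg(scenario)
  cfg <- switch(scenario,
    a = list(l1 = TRUE,  l2 = TRUE,  l3 = FALSE),
    b = list(l1 = FALSE, l2 = TRUE,  l3 = FALSE),
    c = list(l1 = TRUE,  l2 = FALSE, l3 = FALSE),
    d = list(l1 = TRUE,  l2 = TRUE,  l3 = TRUE))
  model <- photo_model(params, loop1_on = cfg$l1, loop2_on = cfg$l2,
                       loop3_on = cfg$l3)
  base <- if (scenario == "b") list(k4 = scenario_b_background)
          else list(k4 = 0)
  ph1 <- utils::modifyList(base, list(k1 = 0, k2 = 1))
  ph2 <- utils::modifyList(base, list(k1 = 7, k2 = 0))
  ph3 <- utils::modifyList(base, list(k1 = 0, k2 = 7))
  if (scenario == "c") ph3$k3 <- 500
  prot <- perturbation_protocol(
    list(list(start = 0, overrides = ph1),
         list(start = phase_duration, overrides = ph2),
         list(start = 2 * phase_duration, overrides = ph3)),
    total_time = 3 * phase_duration,
    dense_output_step = dense_output_step)
  simulate_model(model, prot)
}

#' Printed reference steady states of the photoreceptor model
#'
#' The steady-state concentrations used for leak calibration and
#' self-consistency checks, with the feedback-loop configuration they belong
#' to.
#'
#' @return Named list of reference states (`cGMP`, `Ca` in uM, `loops`).
#' @export
photo_reference_states <- function() .PHOTO_REFERENCE_STATES
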