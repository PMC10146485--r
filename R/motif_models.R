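# The eight basic integral-feedback controller motifs.
#
# Each motif couples a controlled variable A to a controller (manipulated)
# variable E through a negative feedback.  Integral control enters either by
# zero-order (saturated Michaelis-Menten) removal of E, or -- for m2 -- by an
# antithetic pair E1/E2 removed in a bimolecular reaction.  In both cases the
# steady state of A is a set-point fixed by rate-constant ratios, independent
# of the perturbation and background loads.

.MOTIF_IDS <- paste0("m", 1:8)

# Fig-1 taxonomy: inflow controllers compensate removal of A, outflow
# controllers compensate addition; the compensatory flux is driven either by
# direct activation through E or by derepression (E is an inhibitor).
.MOTIF_INFO <- list(
  m1 = list(flow = "inflow",  comp = "activation",   pert = "k2", bg = "k4"),
  m2 = list(flow = "inflow",  comp = "derepression", pert = "k2", bg = "k4"),
  m3 = list(flow = "inflow",  comp = "activation",   pert = "k2", bg = "k4"),
  m4 = list(flow = "inflow",  comp = "derepression", pert = "k2", bg = "k4"),
  m5 = list(flow = "outflow", comp = "activation",   pert = "k1", bg = "k3"),
  m6 = list(flow = "outflow", comp = "derepression", pert = "k1", bg = "k3"),
  m7 = list(flow = "outflow", comp = "activation",   pert = "k1", bg = "k3"),
  m8 = list(flow = "outflow", comp = "derepression", pert = "k1", bg = "k3")
)

# parameters each motif actually uses (beyond these, extra names are rejected)
.MOTIF_PARS <- list(
  m1 = c("k1","k2","k3","k4","k5","k6","k7"),
  m2 = c("k1","k2","k3","k4","k5","k6","k7","k8"),
  m3 = c("k1","k2","k3","k4","k5","k6","k7","k8"),
  m4 = c("k1","k2","k3","k4","k5","k6","k7","k8","k9"),
  m5 = c("k1","k2","k3","k4","k5","k6","k7"),
  m6 = c("k1","k2","k3","k4","k5","k6","k7","k9"),
  m7 = c("k1","k2","k3","k4","k5","k6","k7","k8"),
  m8 = c("k1","k2","k3","k4","k5","k6","k7","k8","k9")
)
.ANTITHETIC_PARS <- c("k1","k2","k3","k4","k5","k6","k7","k8")

# Right-hand sides, state = (A, E) or (A, E1, E2), p a named numeric vector.
.MOTIF_RHS <- list(
  m1 = function(t, y, p) {
    A <- y[[1L]]; E <- y[[2L]]
    list(c(p[["k1"]] - (p[["k2"]] + p[["k4"]]) * A + p[["k3"]] * E,
           p[["k5"]] - A * p[["k6"]] * E / (p[["k7"]] + E)))
  },
  m2 = function(t, y, p) {
    A <- y[[1L]]; E <- y[[2L]]
    list(c(p[["k1"]] - (p[["k2"]] + p[["k4"]]) * A +
             p[["k3"]] * p[["k8"]] / (p[["k8"]] + E),
           p[["k5"]] * A - p[["k6"]] * E / (p[["k7"]] + E)))
  },
  m3 = function(t, y, p) {
    A <- y[[1L]]; E <- y[[2L]]
    list(c(p[["k1"]] - (p[["k2"]] + p[["k4"]]) * A + p[["k3"]] * E,
           p[["k5"]] * p[["k8"]] / (p[["k8"]] + A) -
             p[["k6"]] * E / (p[["k7"]] + E)))
  },
  m4 = function(t, y, p) {
    A <- y[[1L]]; E <- y[[2L]]
    list(c(p[["k1"]] - (p[["k2"]] + p[["k4"]]) * A +
             p[["k3"]] * p[["k9"]] / (p[["k9"]] + E),
           p[["k5"]] - p[["k6"]] * (p[["k8"]] / (p[["k8"]] + A)) *
             E / (p[["k7"]] + E)))
  },
  m5 = function(t, y, p) {
    A <- y[[1L]]; E <- y[[2L]]
    list(c(p[["k1"]] + p[["k3"]] - p[["k2"]] * A - p[["k4"]] * A * E,
           p[["k5"]] * A - p[["k6"]] * E / (p[["k7"]] + E)))
  },
  m6 = function(t, y, p) {
    A <- y[[1L]]; E <- y[[2L]]
    list(c(p[["k1"]] + p[["k3"]] - p[["k2"]] * A -
             p[["k4"]] * A * p[["k9"]] / (p[["k9"]] + E),
           p[["k5"]] - p[["k6"]] * A * E / (p[["k7"]] + E)))
  },
  m7 = function(t, y, p) {
    A <- y[[1L]]; E <- y[[2L]]
    list(c(p[["k1"]] + p[["k3"]] - p[["k2"]] * A - p[["k4"]] * A * E,
           p[["k5"]] - (p[["k6"]] * E / (p[["k7"]] + E)) *
             (p[["k8"]] / (p[["k8"]] + A))))
  },
  m8 = function(t, y, p) {
    A <- y[[1L]]; E <- y[[2L]]
    list(c(p[["k1"]] - p[["k2"]] * A + p[["k3"]] -
             p[["k4"]] * A * p[["k9"]] / (p[["k9"]] + E),
           p[["k5"]] * p[["k8"]] / (p[["k8"]] + A) -
             p[["k6"]] * E / (p[["k7"]] + E)))
  }
)

# antithetic m2: E1 inhibits the compensatory inflow, E2 is produced at a
# constant rate k6 and annihilates E1 bimolecularly (rate k7)
.M2_ANTITHETIC_RHS <- function(t, y, p) {
  A <- y[[1L]]; E1 <- y[[2L]]; E2 <- y[[3L]]
  ann <- p[["k7"]] * E1 * E2
  list(c(p[["k1"]] - (p[["k2"]] + p[["k4"]]) * A +
           p[["k3"]] * p[["k8"]] / (p[["k8"]] + E1),
         p[["k5"]] * A - ann,
         p[["k6"]] - ann))
}

.motif_set_point <- function(motif_id, p) {
  switch(motif_id,
    m1 = p[["k5"]] / p[["k6"]],
    m2 = p[["k6"]] / p[["k5"]],
    m3 = p[["k8"]] * (p[["k5"]] / p[["k6"]] - 1),
    m4 = p[["k8"]] * (p[["k6"]] / p[["k5"]] - 1),
    m5 = p[["k6"]] / p[["k5"]],
    m6 = p[["k5"]] / p[["k6"]],
    m7 = p[["k8"]] * (p[["k6"]] / p[["k5"]] - 1),
    m8 = p[["k8"]] * (p[["k5"]] / p[["k6"]] - 1),
    stop("unknown motif id: ", motif_id)
  )
}

#' Classify a controller motif
#'
#' Returns the flow class (whether the compensatory flux adds to or removes
#' the controlled variable) and the compensation mode (whether the controller
#' species drives that flux by direct activation or by derepression).
#'
#' @param motif_id One of `"m1"` ... `"m8"`.
#' @return A list with elements `flow_class` (`"inflow"` or `"outflow"`) and
#'   `compensation` (`"activation"` or `"derepression"`).
#' @export
#' @examples
#' classify_motif("m2")
classify_motif <- function(motif_id) {
  if (!is.character(motif_id) || length(motif_id) != 1L ||
      !motif_id %in% .MOTIF_IDS) {
    stop("unknown motif id: ", paste(motif_id, collapse = ", "))
  }
  info <- .MOTIF_INFO[[motif_id]]
  list(flow_class = info$flow, compensation = info$comp)
}

#' Build a controller motif model
#'
#' Constructs one of the eight basic integral-feedback motifs as a simulable
#' model object: ODE right-hand side, class labels, closed-form set-point and
#' the conventional mapping of which rate parameter carries the step
#' perturbation and which the constant background.
#'
#' Integral control is implemented by zero-order removal of the controller
#' species E (Michaelis constant `k7` much smaller than the operating E
#' level), or, for m2 only, by antithetic control: two controller species
#' E1/E2 annihilating in a bimolecular reaction with rate constant `k7`,
#' E2 being produced at the constant rate `k6`.
#'
#' @param motif_id One of `"m1"` ... `"m8"`.
#' @param pars Named numeric vector of nonnegative rate parameters
#'   (`k1` ... `k9` as used by the motif).  Parameters the motif uses but that
#'   are not supplied default to 0, except the Michaelis constant `k7`
#'   (zero-order mode), which defaults to `1e-6` au.
#' @param integral_mode `"zero_order"` (default) or `"antithetic"`
#'   (m2 only).
#' @return An object of class `controller_model` with fields `motif_id`,
#'   `integral_mode`, `pars`, `flow_class`, `compensation`, `state_names`,
#'   `set_point`, `perturbation_name`, `background_name` and the right-hand
#'   side function `rhs`.
#' @export
#' @examples
#' m <- build_motif("m1", c(k2 = 1, k3 = 1, k5 = 3, k6 = 1))
#' m$set_point  # 3
build_motif <- function(motif_id, pars,
                        integral_mode = c("zero_order", "antithetic")) {
  integral_mode <- match.arg(integral_mode)
  if (!is.character(motif_id) || length(motif_id) != 1L ||
      !motif_id %in% .MOTIF_IDS) {
    stop("unknown motif id: ", paste(motif_id, collapse = ", "))
  }
  if (integral_mode == "antithetic" && motif_id != "m2") {
    stop("antithetic integral control is only defined for motif m2")
  }
  wanted <- if (integral_mode == "antithetic") .ANTITHETIC_PARS
            else .MOTIF_PARS[[motif_id]]
  pars <- unlist(pars)
  if (length(pars) && (is.null(names(pars)) || any(names(pars) == ""))) {
    stop("'pars' must be a named numeric vector")
  }
  extra <- setdiff(names(pars), wanted)
  if (length(extra)) {
    stop("parameters not used by ", motif_id, ": ", paste(extra, collapse = ", "))
  }
  if (any(!is.finite(pars)) || any(pars < 0)) {
    stop("all rate parameters must be finite and >= 0")
  }
  full <- stats::setNames(numeric(length(wanted)), wanted)
  if (integral_mode == "zero_order") full[["k7"]] <- 1e-6
  full[names(pars)] <- pars

  if (integral_mode == "zero_order" && full[["k7"]] <= 0) {
    stop("zero-order integral control requires Michaelis constant k7 > 0")
  }
  if (integral_mode == "antithetic" && full[["k7"]] <= 0) {
    stop("antithetic control requires bimolecular rate constant k7 > 0")
  }

  set_point <- .motif_set_point(motif_id, full)
  if (!is.finite(set_point) || set_point <= 0) {
    stop("motif ", motif_id, " has no positive set-point for these ",
         "parameters (required rate-constant ratio factor is <= 0)")
  }

  info <- .MOTIF_INFO[[motif_id]]
  model <- structure(
    list(
      kind = "motif",
      motif_id = motif_id,
      integral_mode = integral_mode,
      pars = full,
      flow_class = info$flow,
      compensation = info$comp,
      state_names = if (integral_mode == "antithetic") c("A", "E1", "E2")
                    else c("A", "E"),
      controlled = "A",
      set_point = set_point,
      perturbation_name = info$pert,
      background_name = info$bg,
      rhs = if (integral_mode == "antithetic") .M2_ANTITHETIC_RHS
            else .MOTIF_RHS[[motif_id]]
    ),
    class = "controller_model"
  )

  # zero-order validity: k7 must sit far below the operating E level
  if (integral_mode == "zero_order") {
    ess <- tryCatch(analytic_steady_state(model), error = function(e) NULL)
    if (!is.null(ess) && full[["k7"]] > 0.01 * ess[["E"]]) {
      warning("Michaelis constant k7 = ", full[["k7"]],
              " is not small compared to the operating E level (",
              signif(ess[["E"]], 4), "); removal of E is not zero-order ",
              "and the set-point will not be defended exactly")
    }
  }
  model
}

#' @export
print.controller_model <- function(x, ...) {
  cat("<controller_model> ", x$motif_id,
      " (", x$flow_class, ", ", x$compensation, ", ",
      x$integral_mode, ")\n", sep = "")
  cat("  set-point A_set =", format(x$set_point), "\n")
  cat("  perturbation:", x$perturbation_name,
      " background:", x$background_name, "\n")
  cat("  parameters:", paste(names(x$pars), signif(x$pars, 6), sep = "=",
                             collapse = ", "), "\n")
  invisible(x)
}

.merge_overrides <- function(pars, overrides) {
  if (is.null(overrides) || !length(overrides)) return(pars)
  overrides <- unlist(overrides)
  bad <- setdiff(names(overrides), names(pars))
  if (length(bad)) {
    stop("overrides name unknown parameters: ", paste(bad, collapse = ", "))
  }
  pars[names(overrides)] <- overrides
  pars
}

#' Evaluate a model's rate field
#'
#' Time-derivatives of the model state at a given point, optionally with
#' parameter overrides (e.g. a stepped perturbation value).
#'
#' @param model A `controller_model` (from [build_motif()] or
#'   [photo_model()]).
#' @param state Numeric state vector in the model's state order.
#' @param overrides Named list/vector of parameter values replacing the
#'   model's baseline values for this evaluation.
#' @return Named numeric vector of derivatives.
#' @export
rate_field <- function(model, state, overrides = NULL) {
  stopifnot(inherits(model, "controller_model"))
  state <- unlist(state)
  if (length(state) != length(model$state_names)) {
    stop("state must have length ", length(model$state_names),
         " (", paste(model$state_names, collapse = ", "), ")")
  }
  if (any(!is.finite(state)) || any(state < 0)) {
    stop("state entries must be finite and >= 0")
  }
  p <- .merge_overrides(model$pars, overrides)
  d <- model$rhs(0, state, p)[[1L]]
  stats::setNames(d, model$state_names)
}

#' Closed-form steady state of a controller motif
#'
#' Solves the steady state algebraically: the controlled variable sits at the
#' motif's set-point (integral control), and the controller species E follows
#' from the A-balance.  No integration is performed.
#'
#' @param model A motif `controller_model`.
#' @param perturbation,background Optional values for the motif's step and
#'   background parameters (defaults: the model's baseline values).
#' @param overrides Additional named parameter overrides.
#' @return Named numeric vector: `c(A=, E=)` (zero-order) or
#'   `c(A=, E1=, E2=)` (antithetic).
#' @export
#' @examples
#' m <- motif_preset("fig8")
#' analytic_steady_state(m)  # E = 333.23 at zero background
analytic_steady_state <- function(model, perturbation = NULL,
                                  background = NULL, overrides = NULL) {
  stopifnot(inherits(model, "controller_model"), model$kind == "motif")
  p <- .merge_overrides(model$pars, overrides)
  if (!is.null(perturbation)) p[[model$perturbation_name]] <- perturbation
  if (!is.null(background)) p[[model$background_name]] <- background
  Aset <- .motif_set_point(model$motif_id, p)
  id <- model$motif_id
  info <- .MOTIF_INFO[[id]]
  # net load the compensatory flux must balance at A = A_set
  load <- if (info$flow == "inflow") {
    (p[["k2"]] + p[["k4"]]) * Aset - p[["k1"]]
  } else {
    p[["k1"]] + p[["k3"]] - p[["k2"]] * Aset
  }
  if (load <= 0) {
    stop("no positive steady state: net load on A is <= 0 at the set-point, ",
         "the controller has nothing to compensate")
  }
  if (model$integral_mode == "antithetic") {
    # compensatory inflow k3*k8/(k8+E1) balances the load
    if (load >= p[["k3"]]) {
      stop("no positive solution: derepressed inflow (max ", p[["k3"]],
           ") cannot balance the load ", signif(load, 6))
    }
    E1 <- p[["k8"]] * (p[["k3"]] / load - 1)
    E2 <- p[["k6"]] / (p[["k7"]] * E1)
    return(c(A = Aset, E1 = E1, E2 = E2))
  }
  E <- switch(id,
    m1 = ,
    m3 = load / p[["k3"]],
    m2 = {
      if (load >= p[["k3"]]) {
        stop("no positive solution: derepressed inflow (max ", p[["k3"]],
             ") cannot balance the load ", signif(load, 6))
      }
      p[["k8"]] * (p[["k3"]] / load - 1)
    },
    m4 = {
      if (load >= p[["k3"]]) {
        stop("no positive solution: derepressed inflow (max ", p[["k3"]],
             ") cannot balance the load ", signif(load, 6))
      }
      p[["k9"]] * (p[["k3"]] / load - 1)
    },
    m5 = ,
    m7 = load / (p[["k4"]] * Aset),
    m6 = ,
    m8 = {
      vmax <- p[["k4"]] * Aset
      if (load >= vmax) {
        stop("no positive solution: derepressed outflow (max ", vmax,
             ") cannot balance the load ", signif(load, 6))
      }
      p[["k9"]] * (vmax / load - 1)
    }
  )
  c(A = Aset, E = E)
}

#' Bundled motif parameter presets
#'
#' Parameter sets for the reference experiments, read from the JSON registry
#' shipped with the package (`inst/extdata/motif_presets.json`).
#'
#' @param id Preset id: `"fig4"` (m1), `"fig6"` (m7), `"fig8"` (m2),
#'   `"fig11"` (m8) or `"fig8_antithetic"` (m2 with antithetic control).
#' @return A `controller_model`.
#' @export
motif_preset <- function(id) {
  reg <- .motif_registry()
  if (!id %in% names(reg)) {
    stop("unknown motif preset '", id, "'; available: ",
         paste(names(reg), collapse = ", "))
  }
  entry <- reg[[id]]
  build_motif(entry$motif, unlist(entry$pars),
              integral_mode = entry$integral_mode)
}

.motif_registry <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "motif_presets.json",
                          package = "homeostat", mustWork = TRUE)
      cache <<- jsonlite::read_json(path)
    }
    cache
  }
})
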