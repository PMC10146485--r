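---
title: "Homeostasis under background perturbations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homeostasis under background perturbations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homeostat)
```

## The scientific problem

Cells defend the concentrations of key metabolites against persistent
perturbations.  When the defense is exact -- the controlled variable returns
precisely to a fixed level under any sustained step load -- the underlying
feedback must contain an integral term: a controller species whose
concentration accumulates the error between the controlled variable and its
set-point.  `homeostat` implements two questions around this mechanism:

1. How do the *basic integral controller architectures* respond to a step
   perturbation when a constant **background** load is also present?  Eight
   two-species motifs cover the combinations of inflow vs outflow
   compensation and activation vs derepression signalling.
2. How does the same logic play out in a concrete physiological system, the
   **vertebrate photoreceptor**, where three overlaid calcium feedback loops
   regulate cGMP, and how does the model relate to the psychophysics of
   light adaptation (Weber's and Stevens' laws)?

## The controller motifs

Each motif couples a controlled variable $A$ to a controller species $E$.
For the reference inflow/activation motif m1,

$$\dot A = k_1 - (k_2 + k_4)\,A + k_3 E, \qquad
  \dot E = k_5 - A\,\frac{k_6 E}{k_7 + E},$$

where $k_2$ carries the step perturbation and $k_4$ the constant
background.  When the removal of $E$ is zero-order ($k_7 \ll E$, default
$k_7 = 10^{-6}$ au), $\dot E \approx k_6\,(k_5/k_6 - A)$, i.e. $E$
integrates the error relative to the set-point $A_{set} = k_5/k_6$, and the
steady state of $A$ is independent of both perturbation and background.
The other motifs permute the same ingredients; their set-points are rate
ratios of the $E$ balance ($k_6/k_5$ for m2 and m5, $k_5/k_6$ for m6, and
$k_8(k_6/k_5 - 1)$-type expressions for the motifs where $A$ acts on $E$
through an inhibition constant).  `build_motif()` constructs any of them,
`analytic_steady_state()` solves the $A$ balance in closed form, and
`motif_preset()` returns the four bundled reference parameter sets
(`fig4`, `fig6`, `fig8`, `fig11`).

The equations for m3--m6 are reconstructed by the symmetry of the motif
family (same naming conventions, the unique negative-feedback closure
consistent with each motif's class labels).  No reference parameter values
exist for them, so the package tests them only through properties
(set-point defense, steady-state consistency, class-specific resetting).

For m2 the package also implements **antithetic integral control**: two
controller species $E_1, E_2$ annihilate in a bimolecular reaction,

$$\dot E_1 = k_5 A - k_7 E_1 E_2, \qquad \dot E_2 = k_6 - k_7 E_1 E_2,$$

which forces $A_{set} = k_6/k_5$ at steady state.  The bundled
`fig8_antithetic` preset uses an annihilation constant $k_7 = 10^3$ au
(a package choice; large enough that $E_2$ is slaved and the removal of
$E_1$ operates in its zero-order regime), under which the $A$ trajectories
agree with the zero-order controller to well below 0.5%.

### Response metrics and the two controller classes

For a step applied at $t_0$, `response_metrics()` reports the maximum
excursion $\Delta A_{max}$ (quadratically refined from the dense output,
earliest maximum on ties), the peak time $t_{max}$, and the *resetting
period*.  The resetting period is only loosely defined in the adaptation
literature; the package operationalizes it as the first time after which
the controlled variable stays within a $\pm 1\%$ band around the reference
for the remainder of the window, matching the 1% just-noticeable-difference
convention used throughout.  Unresolved resetting (the band is never
re-entered for good) is flagged, never silently truncated.

Two robust regularities emerge, and are asserted as tests: the excursion
$\Delta A_{max}$ shrinks with background for *all* motifs, while the
resetting period grows with background for activation-type compensation
(m1, m3, m5, m7) and shrinks for derepression-type compensation
(m2, m4, m6, m8).  The mechanism is the phase-1 operating level of $E$:
activation controllers need large $E$ at high backgrounds and zero-order
kinetics caps how fast $E$ can travel.

## Threshold psychophysics

`threshold_stimulus()` finds the "just noticeable" stimulus: the step (or
pulse) height whose maximum excursion equals a target -- by convention 1%
of the defended level.  The search brackets the stimulus at
$[s_0, 10\,s_0]$ (auto-widened tenfold up to twice), runs Brent/bisection
on the simulated excursion, and refines until
$|\Delta_{max}(s^\ast) - \text{target}| < 10^{-5}\,\text{target}$.  Each
objective evaluation is a full ODE solve from the pre-equilibrated state;
the bracket policy keeps the number of solves small.  The simulation
horizon doubles automatically while the excursion peak touches the window
end, so slow responses are never clipped.

`threshold_curve()` tabulates thresholds across a background grid together
with the phase-2 steady-state controller level $E_{ss}$ (held at the
threshold stimulus to convergence).  For all eight motifs the threshold and
the "perception" variable ($E_{ss}$ for activation motifs, $1/E_{ss}$ for
derepression motifs) are linear in the background to $R^2 > 0.999$ --
Weber's law.  `fit_power_law()` fits the general form
$\text{threshold} = a\,x^n + b$ by nonlinear least squares
(Levenberg-Marquardt; starting values $a$ from the endpoint slope, $n=1$,
$b$ from the smallest-background threshold; restarts with jittered starts
on failure) and reports Jacobian-based standard errors.

## The photoreceptor model

State: cGMP, cytosolic calcium $Ca$, and potassium $K$ (concentrations in
micromolar, time in seconds):

$$\dot{cGMP} = k_1 + k_3\frac{k_8^r}{k_8^r + Ca^r} - k_9\,cGMP
  - (k_2 + k_4)\,cGMP\,\frac{Ca^p}{k_{12}^p + Ca^p}$$
$$\dot{Ca} = k_5\,\frac{cGMP^n}{k_{11}^n + cGMP^n}
  \left(\alpha\frac{k_{10}^m}{k_{10}^m + Ca^m} + \beta'\right)
  - k_7\,Ca\,K + v_{leak}$$
$$\dot{K} = k_6 - k_7\,Ca\,K$$

Guanylate cyclase (maximal rate $k_3 = 50\,\mu$M/s) synthesizes cGMP and is
derepressed at low calcium (loop 1); light -- a background $k_4$ plus a
stepped or pulsed $k_2$, both in s$^{-1}$ -- removes cGMP through PDE,
calcium-activated with constant $k_{12}$ (loop 2); cGMP opens CNG channels
letting calcium in, and calcium inhibits the channel (loop 3, amplitudes
$\alpha + \beta' \approx 1$).  NCKX extrudes calcium together with
potassium as a single bimolecular flux $k_7\,Ca\,K$; with the constant
potassium inflow $k_6$ this is exactly an antithetic integral controller
pair, so *in the absence of loop 3* cGMP adapts perfectly with the closed
form set-point

$$cGMP_{set} = k_{11}\left(\frac{b}{1-b}\right)^{1/n},
  \qquad b = \frac{k_6 - v_{leak}}{k_5},$$

implemented by `cgmp_set_point()`.  With loop 3 on, perfect adaptation is
lost (the model's pre-step cGMP level drifts down with background), which
is the price of keeping cytosolic calcium low and non-toxic.

The Hill constants ($k_8, r$; $k_{11}, n$; $k_{10}, m, \alpha, \beta$;
$k_{12}, p, V_{max}$) are the values obtained by fitting the four
normalized dose-response families to published rod/cone measurements;
the synthetic-data module (below) regenerates data of exactly that
structure.  $k_9 = 1\,$s$^{-1}$ and $k_3$ come from earlier
phototransduction modelling, and $k_5 = 100\,\mu$M/s, $k_6 = 0.5\,\mu$M/s,
$k_7 = 2\,\mu$M$^{-1}$s$^{-1}$ place dark cGMP and calcium near their
physiological values.

### Leak calibration

The constant (zero-order) store leak $v_{leak}$ is not among the published
constants; the package *calibrates* it.  At any steady state the K-balance
pins the pump flux at exactly $k_6$, so the calcium balance gives
$v_{leak} = k_6 - k_5\,h(cGMP)\,\zeta(Ca)$ at a known steady state
(`calibrate_leak()`).  The default uses the loops-1+2 reference state
(cGMP $= 7.612\,\mu$M, $Ca = 141.7$ nM), giving
$v_{leak} = 0.2644\,\mu$M/s -- consistent with the literature estimate of
about $0.25\,\mu$M/s and with an independent calibration from the printed
dark state of the full model ($0.2632\,\mu$M/s).  With this single
calibrated number the model reproduces the printed dark steady state
(cGMP $= 9.0419\,\mu$M) to about 0.1%, and all printed operating states of
the pulse experiments to well under 1%.  If $v_{leak} \ge k_6$ the pump can
never absorb the leak: calcium grows without bound.  The package detects
this *integral windup* regime and signals it as a distinct condition class
(`homeostat_windup`).

### Loop dissection conventions

`loop_config()` disables loops by the conventions: loop 1 off via
$k_8 = 10^9\,\mu$M, $r = 1$; loop 2 off via $k_{12} = 0$ (the activation
factor saturates at 1); loop 3 off by replacing the CNG calcium modifier
with the constant 1 -- its exact low-calcium limit, deliberately *not* the
fitted sum $\alpha + \beta' = 1.0074$, so that the closed-form set-point
expression holds exactly.  The 0.74% difference is visible as a
correspondingly small offset when comparing loop-3-off and low-calcium
full-model states.

Two further conventions matter for reproducing the loop experiments:

* **Three-phase dissection runs** (`feedback_scenario()`): phase 1
  $k_1 = 0, k_2 = 1\,$s$^{-1}$; phase 2 $k_1 = 7\,\mu$M/s, $k_2 = 0$;
  phase 3 $k_1 = 0, k_2 = 7\,$s$^{-1}$.  Phase durations are not part of
  the published protocol; 100 s per phase is used, long relative to every
  observed resetting time.  Scenario "b" (loop 2 only) needs a raised
  background ($k_4 = 8\,$s$^{-1}$) to avoid calcium windup; scenario "c"
  (loop 1 only) needs $k_3$ raised to $500\,\mu$M/s in phase 3.
* **Peak-time sweeps of dissected configurations**: the loops-1+3
  configuration has no true steady state for backgrounds above roughly
  $5\,$s$^{-1}$ (the CNG channel closes and the potassium pool winds up
  while cGMP still settles).  The sweeps therefore start each run from the
  *full* model's steady state at that background, matching how the
  dissected arrangements are compared against the full model at identical
  initial concentrations.  Under this convention the loops-1+3 peak time
  shortens monotonically with background while the full model's peak time
  is non-monotone (first shorter, then longer again).

One caption inconsistency is resolved deliberately: the printed dark-state
$K^+$ value equals the printed calcium value scaled by ten, which violates
the K-balance; the package always derives $K = k_6/(k_7\,Ca)$, which
matches the value printed elsewhere for the same state (1.989 uM).

### Weber and Stevens regimes of the pulse thresholds

`photo_threshold_curve()` finds, per background, the 10 ms pulse height of
$k_2$ whose maximum downward cGMP excursion is $0.03\,\mu$M (about 1% of
the dark level).  Fitting $a\,k_4^n + b$ over 15 log-spaced backgrounds in
$[10, 1280]\,$s$^{-1}$ gives an exponent near 1 (Weber regime); over
$[0.1, 10]\,$s$^{-1}$ the exponent drops to about 0.8 (Stevens regime).
Two caveats are documented rather than hidden: the three-parameter power
fit is ill-conditioned on near-linear data ($a$ and $b$ trade off against
$n$), and the exact background grid behind the published fit is unknown --
so exponents carry a tolerance of a few hundredths, and the package's
grids above are fixed once, not tuned.

## The synthetic dose-response generator

`generate_dose_response()` emulates the *structure* of the normalized
measurements behind the Hill constants: log-spaced concentrations
(default 12 points spanning 0.01-100 times the half-saturation constant),
curve values in percent, plus additive homoscedastic Gaussian noise
(default grids and a few-percent noise scale mirror the scatter of such
normalized data; no noise model was published, so homoscedastic Gaussian
is a package choice).  Generation is seeded and deterministic; there are
no unseeded entry points.  `fit_trial_function()` refits each family by
unweighted nonlinear least squares (the original fit weights, if any, are
unknown) and the tests verify noiseless exactness, vanishing bias at low
noise, and approximately nominal confidence-interval coverage over 200
replicates at 3% noise.

What the generator does *not* emulate: digitization error of the original
figures, heteroscedasticity of normalized activities, or correlations
between measurements from a shared preparation.  Passing recovery tests
therefore validate the fitting machinery, not the provenance of the
published constants.

## Numerical choices

* Integration: LSODA (stiff-capable) with `rtol = 1e-8`, `atol = 1e-10`.
  The zero-order removal terms with $k_7 = 10^{-6}$ au are
  near-discontinuous at small $E$, hence the stiff solver.  Halving the
  tolerances moves reported metrics by far less than 0.01%.
* Protocols are integrated phase by phase with an exact restart at every
  boundary, so a 10 ms pulse is applied for exactly its width.
* Extremum refinement: local quadratic interpolation of the dense output
  around the grid extremum; ties resolved to the earliest peak.
* Threshold searches verify the excursion at the returned root and fall
  back to plain bisection until the $10^{-5}$ relative excursion tolerance
  is met.
* Steady states: closed form for the motifs (verified against the rate
  field); for the photoreceptor a single scalar root in $Ca$ (the
  K-balance eliminates $K$, the cGMP balance eliminates cGMP), bracketed
  on $[10^{-9}, 10^{3}]\,\mu$M; relaxation by integration as a generic
  fallback, with the returned state re-verified against the rate field.
* Problem sizes in the test suite are chosen to keep every check a matter
  of seconds: background triples instead of full doubling grids for the
  monotonicity properties, 15-point background grids for the exponent
  fits, 200 Monte-Carlo replicates for interval coverage.

## Known limitations

* Saturable activation kinetics and controller breakdown at high activator
  concentrations are neglected by design (all activations are first-order
  in the activating species).
* The photoreceptor model has no explicit transducin/rhodopsin cascade, no
  sodium/potassium membrane currents and no explicit NCKX transporter
  species or ER store compartment; the leak is a constant, not a
  store-dependent flux.
* Stimuli are piecewise constant; ramps and other growing perturbations
  are out of scope.
* m3-m6 lack published parameter values; all statements about them are
  property-level.
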