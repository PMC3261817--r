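---
title: "The tumour-cord drug-response model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The tumour-cord drug-response model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cordsim)
```

## The model

`cordsim` simulates the action of an anti-cancer drug (parameterized for
doxorubicin) on a *tumour cord*: the idealized cylindrical sleeve of tumour
tissue fed by a single capillary. The cord cross-section is the annulus
$r \in [R_C, R_T]$ ($R_C = 10\,\mu m$ capillary radius, $R_T = 120\,\mu m$
cord radius), with variation in the radial direction only. Three coupled
levels of description are integrated together:

**Interstitial transport.** Free extracellular drug $E(r,t)$ diffuses,
binds reversibly to albumin (bound form $B$, diffusing much more slowly),
and is exchanged with the intracellular compartment through saturable
membrane pumps whose volumetric effect scales with the local cell density
$c_t$:

$$\frac{\partial E}{\partial t} = k_d \nabla^2 E
  + c_t\Big(\frac{V_2 I}{k_2 + I} - \frac{V_1 E}{k_1 + E}\Big)
  - k_3 E + k_4 B, \qquad
\frac{\partial B}{\partial t} = k_{db} \nabla^2 B + k_3 E - k_4 B.$$

The per-cell intracellular concentration $I(r,t)$ obeys
$\partial I/\partial t = V_1 E/(k_1+E) - V_2 I/(k_2+I)$. At the capillary
wall the free drug enters through a Kedem–Katchalsky flux
$F_E = K\,(S(t) - E(R_C)) + K_1$, where $S(t)$ is the prescribed capillary
drug concentration (the dose protocol) and $K_1$ lumps any convective
(Starling) transmural flow; the outer cord boundary is a zero-flux symmetry
boundary, and bound drug does not cross the wall. Interstitial convection
is neglected.

**Intracellular signalling.** Drug-induced apoptosis is represented by one
of two interchangeable switch modules mapping $I$ to the activity
$R \in [0,1]$ of a signalling intermediate:

* *monostable*: $\dot R = k\,(I^n/(k_h^n + I^n) - R)$ — first-order
  relaxation to a steep Hill function ($n = 10$); one steady state per
  input, fully reversible;
* *bistable*: $\dot R = V_f (1-R)/(K_{m1} + 1 - R)
  + (p + qI)\,k_{fb}\,R(1-R) - V_r R/(K_{m2} + R)$ — activation with
  input-catalysed positive feedback and saturated degradation. Two stable
  branches coexist at basal input; the lower branch is annihilated at a
  saddle-node near $I = 1$, so a sufficiently long supra-threshold
  excursion of $I$ switches the module permanently (hysteresis).

Either module drives the same downstream effector
$\dot R_1 = k_f R (1 - R_1) - k_r R_1$. Apoptosis is triggered at a node
when $R_1$ reaches the threshold $R_{1,th} = 0.9$. In the monostable case
the trigger is an irreversible latch (the commitment lives downstream of
the reversible switch); in the bistable case the trigger simply tracks
$R_1 \ge R_{1,th}$, irreversibility arising — when it does — from the
hysteresis of the switch itself. The two modules are *matched*: the input
at which the monostable steady-state effector reaches threshold
($I \approx 0.944$, closed form) agrees with the bistable fold
($I \approx 1.009$, computed by `bistable_fold_inputs()`) to within ~7%,
and `calibrate_module_match()` reports both threshold and time-to-kill
ratios for any parameter set.

**Population dynamics.** Cell density follows a logistic law
$\dot c_t = (a_1 - a_2)\,c_t - b\,c_t^2$ with growth $a_1 = 0.5$/day,
decay $a_2 = 0.24$/day. When a node's trigger is active its growth rate
drops to $a_{1,triggered}$ (default 0, complete shutdown; an equivalent
added-death-rate variant is available via `death_rate_variant`), making
extinction the only attractor there. Since $a_{1,triggered} < a_2$ is the
only property that matters for the outcome, the default is the simplest
choice.

## Nondimensionalization

Radius is scaled by $R_T$, time by the free-drug diffusion time
$t_s = R_T^2/k_d \approx 0.0254$ h (making the dimensionless free-drug
diffusivity exactly 1 — the natural unit for a transport-limited problem),
extracellular concentrations by $E_{ref} = 0.001\,\mu g/mm^3$
($= 1\,\mu g/ml$), intracellular concentration by $I_{ref} = 1$ ng per
$10^5$ cells, and cell density by $c_{ref} = 10^6$ cells/mm$^3$. Three
unit bridges are applied once, in `nondimensionalize()`:

* $V_1, V_2$ are tabulated per minute, binding rates per hour, population
  rates per day — all are converted to the common $t_s$ unit;
* $k_1 = 0.219\,\mu g/ml$ equals its value in $E_{ref}$ units because
  $1\,\mu g/ml = E_{ref}$;
* the per-cell membrane fluxes (ng per $10^5$ cells) become volumetric
  extracellular rates after multiplication by the cell density expressed in
  $10^5$ cells/mm$^3$; the ng$\to\mu$g factor ($10^{-3}$) cancels exactly
  against $E_{ref}$, leaving the bridge factor $\chi = c_{ref}/10^5 = 10$.
  (The printed form of the extracellular balance is ambiguous about the
  density factor on the uptake term; the verbal description — both cellular
  terms scale with cell density — is the physically consistent reading and
  is what the package implements.)

`redimensionalize()` inverts the map exactly; round-tripping is tested to
$10^{-12}$ relative. With the default growth parameters the untreated
carrying capacity is $(a_1 - a_2)/b = 1.00309\,c_{ref}$. The pre-injection
cord is initialized *at* this logistic equilibrium (conditions are uniform
and stationary before dosing), and all reported/normalized densities
(`c_norm`) divide by it, so the untreated level reads exactly 1.

## The wall permeability K

The capillary-wall permeability $K$ and convective term $K_1$ are the only
constants not fixed by the tabulated parameter set. $K_1$ defaults to 0.
$K$ controls how much drug a bolus delivers, and the model's qualitative
portrait pivots on it: above about 1.4 mm/hr the reference bolus ($S = 4$
for 1.75 h) commits the *entire* cord, below about 1.2 mm/hr it commits
nothing. The default, $K = 1.3$ mm/hr ($3.6\times10^{-5}$ cm/s, within the
physiological range for small-molecule transcapillary permeability), was
calibrated once so that the reference bolus produces the model's
characteristic partial outcome — a dead zone adjacent to the wall with
surviving tissue at the cord periphery — and is not revisited by any test
or scenario. A consequence worth knowing: at this permeability washout
back through the wall is slow, so the monostable module (an integrator
with a ~7 h effector memory) responds mostly to the *total absorbed dose*
of a pulse, while the bistable module also requires the input to stay
beyond its fold long enough to commit. This is why the monostable
partial-kill band in pulse height is narrower than and sits below the
bistable one, and why the two bands do not overlap at a single height:
bolus scenarios therefore use module-appropriate representative heights.

## Numerics

The PDE system is discretized by a conservative finite-volume method of
lines on a uniform radial grid (default 61 nodes): interior nodes carry
the standard second-order discretization of
$(1/r)\,\partial_r(r\,\partial_r \cdot)$, the wall flux enters through a
half-cell balance at the first node (so discrete mass is conserved up to
the capillary exchange exactly — tested to $10^{-12}$), and the outer node
carries the zero-flux closure. The resulting stiff ODE system (7 states
per node, packed E, B, I, R, R1, c, latch in fixed column-major order) is
integrated with `deSolve`'s sparse-Jacobian BDF solver (`lsodes`), default
tolerances `rtol = 1e-8`, `atol = 1e-10`.

Two discrete events are handled exactly rather than smoothed:

* *dose edges* — protocols are piecewise constant, left-closed/right-open;
  the integrator restarts at every segment edge;
* *the monostable latch* — a per-node root function detects the upward
  crossing of $R_1$ through $R_{1,th}$ and an event flips that node's
  latch at the crossing time (verified against a 10× denser solve to
  $10^{-4}$ h), so the growth collapse starts exactly when the threshold
  is reached.

State bounds are enforced by clamping only inside the right-hand side
(values are never modified), and non-negativity/unit-interval invariance
is asserted on whole trajectories in the tests. The model is fully
deterministic: identical configurations give bitwise-identical output, and
doubling the mesh or halving the tolerances moves kill-zone boundaries by
under 1%.

Root finding for the bistable branches uses bracketed bisection on a fixed
fine grid (step $10^{-4}$) polished by `uniroot`, because the saturated
degradation term creates a boundary layer of width $\sim K_{m2} = 0.01$
near $R = 0$ where roots approach each other; stability comes from the
sign of the analytic derivative, with $|d\dot R/dR| < 10^{-10}$ reported
as degenerate (a fold) rather than guessed. Fold inputs are located by
bisection on the branch count and cross-checked against brute-force scans.
The closed-form monostable transient (`monostable_transient()`) is
evaluated by adaptive quadrature with the exponential kept in shifted form
$e^{-k(t-w)}$ to avoid overflow; it doubles as an independent oracle for
the integrator.

## Kill-zone metrics

A node is *committed* when its trigger is active — the latch for the
monostable module, $R_1 \ge R_{1,th}$ for the bistable one. Kill-zone
summaries at finite snapshot times (the 12 h snapshots used throughout the
scenario library) are based on commitment, not on the density itself: with
the default rates a committed cell population has only decayed to roughly
0.75–0.8 of basal by 12 h, so a density floor would see nothing at
snapshot time even where extinction is already inevitable. Density-based
detection against an extinction floor (`basis = "density"`) is kept for
long-time profiles, where `steady_state_diagnostics()` also verifies the
predicted end-state structure: spatially uniform extracellular drug (zero
after a completed bolus, commensurate with $S$ under sustained infusion),
albumin binding at equilibrium ($k_3 E = k_4 B$), pump balance, and every
node at either the basal carrying capacity or extinction. The boundary of
the wall-adjacent dead region is interpolated on the continuous $R_1$
profile for the bistable module and taken as the inter-node midpoint for
the monostable latch; disjoint dead regions separated by living tissue are
reported as a list (the summariser supports them, though they do not arise
under the default calibration).

## Scenario library

`scenario_names()` lists the registered studies; each entry records which
of its values are pinned by the reference dosing conditions (e.g. the
single bolus $S = 4$, 1.75 h; double boluses of 1.5 h; 48 h fractionation
interval with 60 h snapshots) and which are the package's representative
choices spanning the no-kill/partial/full-kill range (pulse-height grids,
fractionation total doses of 7 and 6.5 $E_{ref}\cdot$h for the bistable
and monostable modules, double-bolus heights 3.7 and 3.2, cord radii
120–140 $\mu m$). Representative values were chosen once, from the
calibration scans, and are recorded in the registry itself.

## Problem sizes

Defaults used throughout the package and its test-suite: 61-node grid,
200 h horizons for sustained-infusion studies, 900 h for steady-state
classification (extinction at $a_2 = 0.24$/day is slow), 12 h snapshots
for bolus kill zones. Unit tests use 31–41 nodes where only qualitative
structure is probed; every convergence claim is tested at 61 vs 121 nodes.

## Limitations

The model is a deliberately skeletal systems platform. It contains no
cellular variability, stochasticity, cell-cycle structure, resistance,
cell migration, or mechanical interaction — so killing is all-or-nothing
per location, and fronts are perfectly sharp in parameter space (the
partial-kill bands in pulse height are only a few tenths of an $E_{ref}$
unit wide). Capillary blood flow is not modelled: the wall concentration
$S(t)$ is prescribed directly. Geometry is a single straight cord;
realistic microvascular networks, axial variation and interstitial
pressure fields are out of scope, with transmural convection reduced to
the constant $K_1$. The signalling modules are minimal two-variable
caricatures chosen for their input–output class (threshold + memory), not
mechanistic caspase-network models. Passing the included tests therefore
demonstrates the dynamical-systems structure of the framework — thresholds,
hysteresis, transport-limited dose shaping — not quantitative agreement
with any experimental tumour.
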