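---
title: "Modelling blood flow in myogenically active cerebral arterial networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling blood flow in myogenically active cerebral arterial networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Small cerebral arteries regulate their diameter in response to luminal
pressure: a rise in pressure depolarizes the smooth muscle cells (SMCs) of
the wall, raises intracellular Ca2+, engages Ca2+-sensitization kinases, and
drives actin-myosin cross-bridge cycling and cytoskeletal remodelling until
the vessel actively constricts. This *myogenic tone* stabilizes downstream
flow and perfusion pressure when upstream pressure fluctuates. `myoflow`
simulates this behaviour across networks of 1-D compliant vessels by coupling
three sub-models, each exposed as ordinary R functions and integrated by a
compiled time-marching core.

## The pressure-driven signalling network

Seven normalized variables describe one SMC's state: Ca2+ concentration
(`xi0`), ROCK activity (`xi1`), HSP27 phosphorylation (`xi2`), MLCP
phosphorylation (`xi3`), cofilin phosphorylation (`xi4`), LC20 (myosin light
chain) phosphorylation (`xi5`) and G-actin content (`xi6`). Each evolves by
first-order relaxation towards a target produced by a logistic link
(`evaluate_link()`) of its upstream driver:

* `xi0`, `xi1` relax towards sigmoidal functions of luminal pressure
  (`chi0`, `chi1`);
* `xi2`, `xi3`, `xi4` follow ROCK activity (`chi2`, `chi3` inverted —
  ROCK *inactivates* MLCP — and `chi4`);
* `xi5` balances MLCK-driven phosphorylation against MLCP-mediated
  dephosphorylation, `d xi5/dt ∝ chi5 (1 - xi5) - (1 - chi6) xi5`, so its
  quasi-steady value is `chi5 / (chi5 + 1 - chi6)`;
* `xi6` relaxes to the logical-OR target `1 - chi7 chi8`: either
  phosphorylated HSP27 or phosphorylated cofilin suffices to drive actin
  polymerization (G-actin depletion).

The three pressure-facing relaxations share one time constant `tau_c`
(default 10 s, the value that best reproduces wall Ca2+ and diameter response
times in cerebral arteries); all downstream processes are treated as
quasi-instantaneous and pinned to their algebraic targets each step rather
than integrated with a tiny time constant, which would only add stiffness.
`signalling_rhs()` retains the full ODE form (with user-supplied finite
`tau_fast`) for analysis and for the convergence tests.

Two points deserve emphasis because they are modelling choices of this
package:

* **Link wiring and parameters.** The nine logistic links ship with
  illustrative defaults chosen so that (a) the Ca2+, ROCK and downstream
  kinase pathways rise sigmoidally over 10–120 mmHg, (b) ROCK engagement —
  and with it MLCP phosphorylation — stays limited below ~60 mmHg
  (half-activation 85 mmHg), and (c) the cytoskeletal links (`chi7`, `chi8`,
  half-activation 0.3, slope 4) provide a basal F-actin content at low
  pressure. The last point matters mechanically: the actin cortex anchors
  the contractile fibres, and with no basal anchoring the filament sliding
  drifts unopposed under cross-bridge cycling. All links are configurable
  (`link_table()`).
* **F-actin content.** The cortex stiffness needs the F-actin level `xi7`,
  which we define as `1 - xi6` (the complement of the G-actin content).

Pharmacology enters as a mode switch, not a concentration-response model:
`"diltiazem"` replaces the pressure-to-Ca2+ link by a small residual
stretch-operated component (default amplitude 0.15), and `"zero_ca"` forces
the Ca2+ target to zero, abolishing tone.

## Contractile machinery and wall mechanics

Within each SMC, chains of contractile units (CUs) in series with actin
cortex springs form contractile fibres. The state variable is the normalized
relative actin-myosin filament sliding `u_fs`, with first-order dynamics

```
d u_fs / dt = (Fa - Fc) / tau_m + (d lambda_theta / dt) / (2 N_CU),
```

where `Fc` is the driving force of the cycling cross-bridges (proportional
to the LC20 phosphorylation `xi5` and to the Gaussian filament-overlap factor
`filament_overlap()`), and `Fa` is the elastic reaction of the fibre: the
total elongation `lambda_theta - 1 - 2 N_CU u_fs` times the series stiffness
`ktCU kAC / (2 ktCU + kAC)` of the CU chain (`ktCU`, again overlap- and
`xi5`-dependent) and the cortex springs (`kAC`, a Hill function of `xi7`).
Because the sliding equation divides `Fa - Fc` by a time constant in
seconds, the contractile forces are kept in normalized (reference
cross-bridge) units; the surface density of contractile fibres `N_CF`
(dyn/cm^2) converts the fibre force to an active first Piola-Kirchhoff
stress. `tau_m` defaults to 6.188e-2 s, 1e3 times the mouse descending-aorta
estimate of 6.188e-5 s, the combination that best matches cerebral-artery
response times; the solver is equally stable at the stiffer original value
because the sliding dynamics are integrated implicitly.

The wall is an axisymmetric incompressible hyperelastic thick-walled tube
whose volume is occupied by `n_layers` (default 5) concentric SMC layers.
Finite-strain kinematics (`kinematics()`) map reference radii to deformed
radii; the passive energy is an isotropic ground matrix plus an
exponentially stiffening circumferential fibre family (`passive_params()`),
the active energy is the potential of the fibre reaction force. Radial
momentum balance links luminal pressure to the transmural stress integral
(`transmural_pressure()`), evaluated at the mid-radius of each layer with
interpolatory quadrature weights: composite Simpson weights cannot be
centred on layer midpoints, so the package uses the unique
Newton–Cotes-type rule on those abscissae (exact to degree `n_layers - 1`,
and within 0.5% of a 1001-point reference over the working area range — a
tested property). Each layer sees its own circumferential stretch, hence its
own sliding equilibrium; the signalling state is stored per cross-section
because the default wiring is driven by luminal pressure alone, which all
layers share.

The time-discretized wall system (`wall_residuals()`) treats both `d u_fs/dt`
and `d lambda_theta/dt` with the two-step backward difference (backward Euler
on the first step) and evaluates the forces implicitly at the new time level,
solving the `n_layers + 1` unknowns (per-layer sliding plus luminal area)
with a damped Newton iteration. Implicitness is essential: the sliding time
constant is orders of magnitude below the usable time steps. The *averaged
active stress* variant collapses the sliding unknowns to one, driven by the
thickness-averaged stretch; in the pressure integral the active term then
uses the layer-local stretch with the shared sliding value, which keeps the
variant as close as possible to the layer-resolved model (steady diameters
agree within 2% for thin walls, a tested property). Vessel compliance
`C_A = dA/dP` is recovered by a centred difference of the
frozen-intracellular-state pressure-area relation with a perturbation
equivalent to 0.1 mmHg — small against the 10–120 mmHg working range yet far
above solver noise.

Two numerical safeguards are worth knowing about. First, the quasi-static
pressure-area relation of a myogenically active wall can fold (the classic
limit-point of a soft pressurized tube, sharpened by active stress), so a
vessel can snap between a distended and a constricted state; when Newton
loses the root it restarts from a spread of area guesses. The model is
genuinely bistable in parts of the pressure range — simulated vessels may
settle on either branch depending on their loading history, which is also
why network protocols establish tone at baseline pressure before applying a
surge. Second, solver failures carry the simulated time and node in their
message.

## 1-D network haemodynamics

Blood flow follows the 1-D mass and momentum equations in pressure-flow
form with a Poiseuille profile, constant viscosity (0.05 poise) and density
(1.04 g/cm^3). The equations are linearized in time: each two-node element
contributes a mass row and a momentum row (`element_matrices()`) built by
trapezoidal spatial integration with coefficients (area, compliance) frozen
at the current iterate, BDF2 in time (backward Euler at start-up). The
convective term is explicit, extrapolated to the new time level from the two
previous steps; the friction term `8 pi mu Q / A^2` is kept *implicit* with
its coefficient frozen at the current area. This matters at arteriolar
scale: the viscous relaxation time `rho A / (8 pi mu)` is tens of
microseconds, far below the working time steps, so an explicit friction term
would be unconditionally unstable. The global system — element rows,
junction rows (static pressure continuity and mass conservation), an inlet
pressure row and outlet rows `P - Z Q = Pout` — is solved directly after
row/column equilibration (pressure and flow columns differ by ~7 orders of
magnitude in CGS units). The scheme shows second-order self-convergence on
a smooth single-vessel problem, and junction mass conservation at the level
of the linear-solver rounding (both tested).

Terminal vessels end in a characteristic impedance `Z = rho c / A`
(`characteristic_impedance()`), with the pulse wave speed
`c = sqrt(A / (rho C_A))` evaluated once from the t = 0 state, so outgoing
waves are absorbed rather than reflected; a matched termination passes less
than 5% of an incident pulse back (tested on a synthetic larger vessel —
at true arteriolar scale friction damps pulses within millimetres, so no
reflection test is physically possible there).

## Fluid-wall coupling

Each time step exchanges: flow solve (new nodal `P`, `Q`) → per-node
signalling step driven by the new nodal pressure → per-node wall solve (new
`u_fs`, `A`) → compliance update. In *weak* coupling this sequence runs
once; in *strong* coupling it is fixed-point iterated, with the luminal
areas of all network nodes as the iterate, until the root mean square
relative error (`rmsre()`) between successive area iterates falls below
`epsilon` (default 1e-6). Divergence is a first-class outcome: the solver
aborts with diagnostics if the iterate RMSRE grows ten times in a row or the
iteration cap (default 50) is reached. The signalling step is a two-step
Adams–Bashforth update whose new-step derivative uses the current pressure
iterate — under constant or piecewise-constant pressure this is exactly
AB2, and it lets the intracellular state participate in the fixed-point
loop as the coupling prescribes.

Initial conditions for every run: nodal pressure equal to the first inlet
value, zero flow, all signalling variables zero, sliding `-2e-2`, unit
circumferential stretch, and the compliance of that configuration.

## Study conditions and defaults

The bundled network (`default_mca_tree()`) is an idealized symmetric tree of
a rat middle cerebral artery and three daughter generations: load-free outer
diameter 135 um at the root, daughter diameters scaled by
`sqrt(1.35 / 2)` per generation (parent-to-daughters area ratio 1.35),
thickness ratios 90/80/70% of the root value for G1–G3, two axial elements
per vessel, outlet pressure 50 mmHg, external pressure 10 mmHg. Values the
morphology sources do not pin down are repository defaults, stated as such:
vessel lengths 0.40/0.30/0.20/0.15 cm (plausible for the rat MCA tree) and a
root thickness-to-mean-radius ratio of 0.20 (mid-range for muscular
cerebral arteries). The passive constants (`c0 = c1 = 4e4` dyn/cm^2,
`c2 = 8`) give a compliant low-pressure regime stiffening beyond ~40 mmHg
with pulse wave speeds of a few m/s, and the contractile defaults produce
full myogenic constriction capacity in the 40–120 mmHg range; both sets are
package defaults calibrated once for realistic behaviour, not measured
values, and all are overridable.

The documented variable-mean periodic inlet signal
(`default_inlet_signal()`) superposes a heart-rate-like sinusoid (period
0.2 s, amplitude 8 mmHg) on a piecewise-linear mean sweeping
60 → 90 → 70 → 85 mmHg over 10 s. It is a pure function of its
specification — no random component — so every run is exactly reproducible;
the seed argument in the signal specification is reserved for user-defined
randomized protocols.

## Numerical experiments

* `single_vessel_protocol()` clamps the luminal pressure of one cannulated
  segment (no flow solve) and records diameter and Ca2+ traces at
  `dt = 0.5 s`, adequate because the slow signalling dominates;
  `tau_sweep()` grids `tau_c` and `tau_m` and scores each run against a
  user-supplied reference trace (`rmsre_score()`). The package bundles no
  experimental recordings.
* `settings_comparison()` reruns the same network problem under the five
  standard numerical settings (time step 1e-4/2e-4/2.5e-4 s, strong/weak
  coupling, active-stress averaging) and scores each against the first by
  per-generation mid-vessel flow and area RMSRE on a shared 1e-2 s sampling
  grid, excluding the t = 0 sample where the reference flow is identically
  zero.
* `autoregulation_curve()` establishes tone at a baseline pressure, ramps
  the inlet to each final pressure, and tabulates the steady root-vessel
  flow and per-generation diameter ratio (control over zero-Ca). All runs
  share the pre-ramp trajectory, so it is computed once per calcium mode
  and the ramps continue from the stored state — bit-identical to running
  each case end to end, at a fraction of the cost. A drift detector flags
  runs that have not settled.

The test suite and the acceptance script run these protocols at reduced
horizons — 10 s for the settings comparison, a 30 s baseline with recording
at 90 s for the autoregulation curve — chosen so the full suite completes
in minutes while the compared quantities are converged to well within the
asserted tolerances.

## What the defaults do and do not emulate

The synthetic study conditions reproduce the *structure* of ex-vivo
myography and network perfusion experiments: pressure-clamp step trains,
variable-mean periodic inlet signals, pressure surges against a fixed
downstream pressure. They do not emulate measured geometry of any individual
animal, flow- or shear-dependent tone (deliberately absent from the model),
metabolic regulation, parenchymal arteriole beds (truncated behind the
outlet impedance), or blood rheology beyond constant Newtonian viscosity.
Passing tests therefore demonstrate internal correctness — conservation,
convergence, constitutive identities, qualitative physiology (constriction
under tone, flattened flow-pressure dependence) — not agreement with any
particular laboratory recording; the trace-scoring hooks exist precisely so
users can bring their own recordings.

## Known limitations

* Bistability: in parts of the pressure range the wall has coexisting
  distended and constricted equilibria; outcomes legitimately depend on
  loading history, and snap-throughs produce locally steep transients.
* Weak coupling is only conditionally stable; at the default network and
  wall stiffness the usable time step is a few 1e-4 s. Strong coupling
  tolerates larger steps but costs iterations.
* The quasi-steady treatment of `xi3..xi6` assumes their true time constants
  are far below `tau_c`; systems where that fails need finite `tau_fast`
  and an external integrator built on `signalling_rhs()`.
* One signalling state per cross-section: layer-resolved signalling would
  require stretch- or stress-driven links, which the default wiring does not
  contain.
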