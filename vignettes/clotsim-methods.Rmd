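---
title: "Methods: continuum clotting under flow in clotsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: continuum clotting under flow in clotsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`clotsim` simulates the coupled physics of blood clot formation in a
two-dimensional vessel segment: plasma flow, platelet aggregation against a
hard packing limit, ADP secretion by newly bound platelets, and a reduced
enzymatic coagulation cascade triggered at an injured wall patch.  All
internal units are micrometres, seconds, nanomolar, and platelets/µm³.

## Fluid: Navier–Stokes–Brinkman

Plasma is an incompressible Newtonian fluid,

$$\rho\,\partial_t \vec u + \rho(\vec u\cdot\nabla)\vec u
  = -\nabla p + \mu \nabla^2 \vec u - \mu\,\alpha(\theta_B)\,\vec u,
  \qquad \nabla\cdot\vec u = 0,$$

where the Darcy term $-\mu\alpha\vec u$ is the frictional resistance of the
growing platelet mass.  The inverse permeability follows the Carman–Kozeny
relation
$\alpha(\theta_B) = C_{CK}\, 0.6\,\theta_B^2/(1-0.6\,\theta_B)^3$ with
$C_{CK} = 10^6\,\mathrm{mm^{-2}} = 1\,\mathrm{\mu m^{-2}}$, and
$\theta_B = (P_{b,a}+P_{se,a})/P_{max}$ is the bound platelet fraction.
The solver works in kinematic form ($p/\rho$, $\nu = \mu/\rho$); the printed
momentum equation carries the dynamic viscosity in the Darcy term, so in
kinematic form the term is $-\nu\,\alpha\,\vec u$.

Discretisation: a staggered (MAC) arrangement — x-velocity on vertical
faces, y-velocity on horizontal faces, pressure at cell centres — rather
than a colocated arrangement with Rhie–Chow interpolation.  The staggered
form eliminates checkerboard pressure modes with no extra machinery while
preserving the two contracts that matter: the PISO predictor/corrector
structure, and the implicit treatment of the Darcy term using $\theta_B$
from the previous time step.  Each step performs one momentum solve
(backward-Euler diffusion, implicit Darcy diagonal, explicit conservative
central advection, lagged pressure gradient) and `n_correctors` (default 2)
pressure–velocity corrections.  The corrector's face conductances are
$A_f / (1/\Delta t + \nu\alpha_f)$, so highly resistive regions receive
proportionally less corrective flux — the pressure field "feels" the clot.
After correction the discrete divergence is at the direct-solver level
(~1e-13, far below the 1e-8 normalised tolerance).

## Platelets: hindered transport with a hard packing limit

Four number-density species: mobile unactivated $P_{m,u}$, mobile activated
$P_{m,a}$, bound activated $P_{b,a}$, and subendothelium-bound activated
$P_{se,a}$.  Mobile species obey

$$\partial_t P = -\nabla\cdot\big[W(\theta_T)\,(\vec u P - D_P \nabla P)\big] + S,$$

bound species are immobile ($S$ only).  $\theta_T$ is the total platelet
fraction.  The hindrance is
$W(\theta_T) = \tanh\!\big(\pi(1-\theta_T)\big)/\tanh(\pi)$ for
$\theta_T<1$ and $0$ otherwise — smooth, non-increasing, with $W(0)=1$
exactly and $W=0$ at the packing limit.  (The unnormalised
$\tanh(\pi(1-\theta_T))$ gives $W(0)=\tanh\pi\approx0.9963$; we divide by
$\tanh\pi$ so the dilute limit is exactly unhindered.)

The packing bound $\theta_T \le 1$ is enforced by the face interpolation of
$\theta_T$: **downwind** with respect to the flux for the advective
multiplier (flow is only hindered by thrombus downstream — if the receiving
cell is packed, $W=0$ shuts the inflow), and **localMax** (maximum of the
two adjacent cells) for the diffusive multiplier (diffusion through a
packed cell is blocked from both sides).  Faces with exactly zero flux fall
back to linear interpolation under the directional schemes.

Source terms (all transfers antisymmetric, so platelet number is conserved
exactly):

* **activation** $P_{m,u}\to P_{m,a}$ at rate $A_{ADP}([ADP]) + A_{E2}([E_2])$
  with Hill kinetics $A(c) = k^{pla} c/(c^*+c)$;
* **adhesion** (mobile $\to P_{se,a}$) at rate
  $k_{adh}\,H_{adh}(\vec x)\,(1-P_{se,a}/P_{se}^{cap})_+ (1-\theta_T)_+$,
  where $H_{adh}$ is a binary indicator of cells whose centre lies within a
  platelet diameter $P_{diam}=3\,\mathrm{\mu m}$ (Euclidean
  centre-to-face distance) of the `injuryWalls` patch.  A sharp indicator
  was chosen over a smoothed profile; the form is isolated behind
  `compute_adhesion_region()` and can be swapped.  The subendothelial
  capacity $P_{se}^{cap}$ (default 0.05 platelets/µm³, roughly a platelet
  monolayer distributed over the wall cell) caps direct wall adhesion;
* **cohesion** $P_{m,a}\to P_{b,a}$ at rate
  $k_{coh}\,g(\eta)\,\theta_B\,(1-\theta_T)_+$: binding requires locally
  present bound platelets (the local $\theta_B$ factor — a local surrogate
  for a neighbourhood operator) and is modulated by the saturating binding
  affinity $g(\eta)=\eta/(\eta^*+\eta)$.  The signal $\eta$ is configurable
  (`eta_source`); the shipped cases use platelet-bound thrombin E2b, so
  aggregates consolidate where coagulation succeeds.  `g_bypass = 1` forces
  $g\equiv1$ for testing.

Because both bound-species sources are non-negative and strictly local,
$\theta_B$ grows monotonically and only inside the adhesion support — the
localisation property the regression tests assert.

## ADP release

$\partial_t[ADP] = -\nabla\cdot(\vec u[ADP] - D_{ADP}\nabla[ADP]) +
\sigma_{release}$, with

$$\sigma_{release}(\vec x, t) = \int_0^{\tau_f} \hat A\,R(\tau)\,
  \partial_t\big(P_{b,a}+P_{se,a}\big)(\vec x, t-\tau)\,d\tau .$$

$R(\tau)$ is a Gaussian bell centred at 3 s normalised to unit mass on
$\tau\ge0$: $R(\tau) = e^{-(\tau-3)^2}/Z$, $Z=(\sqrt\pi/2)(1+\mathrm{erf}\,3)$.
$Z$ differs from $\sqrt\pi$ only by the negligible $\tau<0$ tail
(1.1e-5); the explicit normalisation makes the released mass per platelet
exactly $\hat A$.  The window is truncated at $\tau_f$ (`sigma_Tf`, 6 s).
The newly-bound rate is sampled every $\Delta\tau$ (`sigma_dt`, 0.05 s) as
$P_{max}(\theta_B^n - \theta_B^{n-1})/\Delta t$ into a ring buffer, and the
integral is a trapezoid sum over the buffer ($O(\Delta\tau^2)$, verified
against adaptive quadrature).  Negative sampled rates (unbinding) are
clipped to zero inside the quadrature — release cannot be negative — and
flagged.  Missing history before start-up counts as zero, so
$\sigma(0)=0$.  $\hat A$ is configured in mol/platelet (default
2.4e-17); the bridge to nM/s is one fixed conversion factor.  The ADP
equation is advanced outside the fractional-step reaction system because
its source only changes at the $\Delta\tau$ cadence.

## Coagulation: a 12-species reduced cascade

Species are tagged by habitat: `fluidPhase` species advect and diffuse,
`pltBound` species ride on activated platelet surfaces (immobile, capacity
limited), `seBound` species live only on the injured wall.  The default
split (the count of 12 is asserted by the registry):

| category | species |
|---|---|
| fluidPhase (8) | S1, E1, S2, E2, I1, I2, E1·I1, E2·I2 |
| pltBound (3) | E1b, S2b, E2b |
| seBound (1) | E0 |

Wiring: the wall enzyme E0 converts fluid substrate S1 into enzyme E1 at
`injuryWalls` with a Michaelis flux
$\varphi = k_{cat0} E_0 S_1/(K_{M0}+S_1)$ (1:1, E0 catalytic); E1 binds
reversibly to activated-platelet sites ($N_1$ per platelet) as E1b;
substrate S2 binds ($N_2$ sites, shared with E2b) as S2b; S2b is activated
to the thrombin-like bound enzyme E2b by E1b *and* by E2b itself — the
positive feedback loop; E2b releases fluid-phase thrombin E2, which
activates mobile platelets; the fluid inhibitors I1 and I2 irreversibly
neutralise fluid E1 and E2 (bound enzymes are protected, a standard
convention in platelet-surface models).  Binding capacities scale with the
local bound platelet density via free-site factors
$(N_k\,[P_b]-\text{occupied})_+$, so every `pltBound` rate vanishes where
no bound platelets exist.  The inert complexes give four exact linear
invariants (E1-total, S2-total, I1-total, I2-total) that the tests track to
1e-8 along trajectories.

Rate-constant defaults are physiological-order choices calibrated once, at
design time, to reproduce a canonical thrombin-generation curve in a
well-mixed setting: with an E1 seed and pre-bound platelets, lag ≈ 40 s,
burst over ~100 s, peak total thrombin tens of nM; removing the feedback
term leaves only a graded sub-nM response, and increasing it shortens the
lag monotonically.  They are inputs in the configuration dictionary, not
constants of the method.

The **extension recipe** mirrors the two-step procedure for adding a
species: `add_inhibitor_extension(registry, k_I)` registers a fluid-phase
inhibitor I with reaction rate $-k_I\,I\,E_2$ and the inert product
E2\_inh, and appends its rate block to the registry — no solver code
changes.

## Time integration: fractional-step coupling

Each transport step $\Delta t$ (default 1e-3 s):

1. update $\alpha(\theta_B)$ from the previous step's bound fraction;
2. momentum predictor + PISO correctors;
3. conservative transport of every mobile species: explicit upwind
   advection with implicit (backward-Euler) diffusion for the chemicals and
   ADP, explicit diffusion for the mobile platelets (their hindered face
   coefficients change every step, and the platelet cell Fourier number
   $D_P\Delta t/\Delta x^2 \approx 4\times10^{-3}$ makes the explicit step
   stable and accurate while avoiding a refactorisation per step);
4. the coupled reaction system — cascade kinetics, wall surface reaction
   (as wall-cell sources in the reaction stage, the patch-field analogue),
   and platelet state transitions — advanced with classical RK4 applied
   `M_rxn` times (default 2) at $h=\Delta t/M_{rxn}$, all species
   simultaneously;
5. release-history update at the $\Delta\tau$ cadence, then the ADP step.

The splitting is first-order in $\Delta t$; RK4 keeps the stiff-ish
kinetics at their sub-step scale.  Negative concentrations from
advection under/overshoot are clipped to zero at the end of the full step
with the clipped mass logged; in the shipped runs the clipped mass is
exactly zero (upwind advection and backward-Euler diffusion are monotone at
the operating Courant/Fourier numbers, and every kinetic sink is
proportional to its own species).

Implicit operators are 5-point symmetric positive-definite stencils solved
with sparse Cholesky factorisations (CHOLMOD via the Matrix package); the
symbolic analysis is done once per operator and only numeric values are
refreshed, and species sharing an operator (the eight fluid-phase proteins;
the mobile platelet pair) are advanced in one multi-right-hand-side solve.

## Numerical and design choices

* **Time step.** $\Delta t = 10^{-3}$ s for both shipped cases.  At the
  configured inlet (wall shear rate 100 s⁻¹, mid-channel velocity
  1500 µm/s) the advective Courant number is 0.8 on the full mesh and 0.6
  on the reduced mesh, under the warn threshold of 0.9 (`strict` mode
  aborts instead); diffusion is implicit, and reactions sub-step at
  $h=0.5$ ms.
* **Boundary conditions.** Parabolic inflow at the inlet, zero-gradient
  velocity with fixed reference pressure at the outlet, no-slip walls;
  species enter at fixed inlet concentrations and leave by upwind outflow.
  The channel's inlet shear rate is a configuration value: the antecedent
  continuum models operate around 100 s⁻¹ and that is the shipped default.
* **Closed domains** (tests) pin the pressure reference in one cell.
* **Zero-flux tie-break.** Exactly zero face flux under upwind/downwind
  falls back to the linear mean.
* **Mesh scope.** Multi-block rectangular tilings whose union is a uniform
  tensor-product grid; non-conforming interfaces or graded spacing are
  rejected at build time.  Cell ownership of interior faces is by the
  lower-index cell.
* **Problem sizes.** The shipped full case is the 240×60 µm channel at
  128×32 cells with a 90 µm injury patch (600 s of clotting); the reduced
  case is the same physics at 96×24 cells (2.5 µm ≤ $P_{diam}$) run for
  30 s, the configuration exercised end-to-end by the regression tests.
  Verification cases (Poiseuille/Brinkman channels, order studies,
  well-mixed chemistry) use 1-D-like strips and small boxes chosen so each
  study isolates one property.

# Relation to blockMesh-style case definitions

Users coming from OpenFOAM-family solvers define multi-block meshes through
a `blockMeshDict` of shared vertices; `clotsim` uses per-block extents
instead.  The correspondence for the shipped channel (three blocks along the
bottom wall, middle-block bottom edge reactive):

| blockMeshDict concept | clotsim equivalent |
|---|---|
| `vertices` (shared corner list) | implicit: each block gives `x0,x1,y0,y1`; shared edges must coincide exactly |
| `blocks hex (...) (nx ny nz)` | `list(x0=, x1=, y0=, y1=, nx=, ny=)` (unit depth; `nz` absent) |
| `boundary { inlet { faces (...) } }` | `patch_assignments["<block>.<side>"] = "inlet"` |
| injury block's bottom face -> `injuryWalls` | `"2.south" = "injuryWalls"` |
| `constant/inputParameters` dictionary | flat key-value file via `read_input_parameters()` / `write_input_parameters()`, same key names (`sigma_dt`, `sigma_Tf`, `M_rxn`, `num_fluidPhase`, ...) |

`blockMeshDict` files themselves are not parsed, and non-conforming block
interfaces are rejected at build time rather than stitched.

# What the synthetic cases do and do not show

The channel scenario emulates the canonical thrombosis-under-flow
configuration: steady upstream flow, a finite reactive patch, platelet-rich
plasma with physiological platelet counts, and coagulation initiated only
at the wall.  Passing tests demonstrate internal correctness — conservation,
boundedness at the packing limit, convergence orders, localisation, and
agreement with closed-form flows and independent ODE integrations.  They do
not demonstrate fidelity to any particular experiment: red-cell-enhanced
platelet margination is folded into an effective $D_P$, plasma is Newtonian,
aggregation has no shear dependence, the cascade is a 12-species reduction
with order-of-magnitude rate constants, and the geometry is 2-D.  Those are
modelling choices to revisit before quantitative comparison with data.

# Known limitations

* 2-D only; no turbulence, non-Newtonian rheology, or moving boundaries.
* The cohesion kernel is local; a nonlocal neighbourhood operator would be
  needed to model bridging across cells finer than a platelet diameter.
* Fluid-phase proteins share one diffusivity `D_c` by default.
* The fractional-step coupling is first-order in time; halve `dt` (and
  keep `M_rxn`) to check sensitivity of any quantitative result.
* Restart files capture the full solver state (including the release
  history); archives are exact, VTK output is for visualisation only.
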