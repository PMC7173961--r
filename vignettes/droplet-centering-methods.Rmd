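---
title: "Models and methods: centering and symmetry breaking of contraction centers in droplets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: centering and symmetry breaking of contraction centers in droplets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(dropcenter)
```

This vignette is the package's own account of the science it implements:
the governing equations and their assumptions, the numerical scheme, every
calibrated parameter and why it has the value it has, what the synthetic
generators do and do not emulate, and the known limitations. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. The two-phase hydrodynamic model

A spherical droplet of radius $R$ contains a contracting actin network
(density $\rho$, velocity $\mathbf V$) immersed in viscous cytosol
(velocity $\mathbf U$, pressure $P$), with the aggregate represented as an
excluded sphere of radius $a$ whose center sits at distance $d$ from the
droplet center. The model rests on four assumptions:

* **Prescribed contraction.** The network moves centripetally toward the
  aggregate with speed growing linearly with distance from its surface,
  $\mathbf V = -\gamma\,\max(|\mathbf x - \mathbf x_a| - a,\,0)\,\hat
  {\mathbf u}$, and vanishes on the aggregate surface. This is an input,
  not a solved momentum balance: the observed contraction is homogeneous
  and density-independent, so prescribing it avoids committing to an
  active-gel rheology the data do not constrain.
* **First-order turnover.** Network mass obeys
  $\partial_t \rho + \nabla\!\cdot\!(\rho \mathbf V) = k_a - k_d\,\rho$,
  with constant assembly ($k_a$) and disassembly ($k_d$) rates and no
  influx through the droplet shell.
* **Darcy coupling.** The cytosol squeezes through the network's pores;
  the friction per unit volume is proportional to the local relative
  velocity, $\zeta(\rho)\,(\mathbf U - \mathbf V) = -\nabla P$, with the
  cytosol incompressible, $\nabla\!\cdot\!\mathbf U = 0$ (the network
  volume fraction is dilute and neglected in the fluid continuity), and
  no-penetration on both the droplet shell and the aggregate surface.
* **Force on the aggregate.** The friction the network exerts on the fluid
  is transmitted by reaction through the (connected) network onto the
  aggregate: $\mathbf F = -\int \zeta(\rho)(\mathbf V - \mathbf U)\,
  d\Omega$. Pointwise the fluid force balance gives $\zeta(\mathbf V -
  \mathbf U) = \nabla P$, so the same force is the volume integral of the
  pressure gradient; the package computes both and reports their mismatch
  as a discrete third-law check.

### 1.1 The friction law (a deliberate deviation)

The permeability of the mesh must decrease with density, but no functional
form is fixed by the text. The package uses

$$\zeta(\rho) = \zeta_0\,\eta\,\rho^{\alpha}, \qquad \alpha = 0.3
\text{ by default (exposed as } \texttt{zeta\_exp}).$$

The seemingly natural semidilute choice $\alpha = 1$ was implemented first
and *rejected by measurement*: with drag linear in density, doubling the
turnover rates $(k_a, k_d)$ jointly changes the simulated recentering
half-time by ~28% while doubling $\gamma$ changes it by only ~22% — the
inverse of the observed sensitivity hierarchy (centering dynamics nearly
independent of turnover and viscosity, strongly enhanced by contraction).
The mechanism: turnover controls how steeply the density falls toward the
droplet shell (the near-boundary profile is $\rho \approx k_a (R - r) /
(\gamma (R - a))$), and with $\zeta \propto \rho$ that outer shell, which
carries most of the volume, dominates the force integral. Damping the
density dependence restores the observed pattern while keeping the
boundary return ("fountain") flow, which disappears entirely for
density-independent drag ($\alpha = 0$: the pressure solve then has no
reason to route the return flow through the low-density shell). With
$\alpha = 0.3$ the measured half-time changes are: viscosity ×2 → 0%
(exact, because the aggregate drag is also $\propto \eta$), turnover ×2 →
~11%, contraction ×2 → ~41%. The acceptance suite re-measures all three.

### 1.2 Default parameters (calibrations, all overridable)

| parameter | default | why |
|---|---|---|
| $\gamma$ | 0.2 /min | M-phase order of magnitude implied by ~1 min turnover |
| $k_d$ | 1 /min | ~1 min network turnover |
| $k_a$ | 1 (density·/min) | fixes the density scale $\bar\rho = k_a/k_d = 1$ |
| $\eta$ | 1 pN·min/µm² | sets the viscosity scale |
| $\alpha$ (`zeta_exp`) | 0.3 | sensitivity hierarchy, §1.1 |
| $\zeta_0$ | 1.25e-3 | so the peak recentering speed of a 50 µm droplet falls in the observed 5–10 µm/min band (measured 7.3 µm/min) |
| $\Gamma_{agg}$ | $6\pi\,\eta_{eff}\,a$, $\eta_{eff} = \eta$ | minimal overdamped Stokes-like closure |
| `grid_h` | $a/5$ | resolves the aggregate; scales with geometry |

These were fixed once, before the test suite was written, and not
revisited. Every calibration target is a qualitative band, not a number to
hit.

### 1.3 Discretisation

The geometry is exactly axisymmetric, so the solver works on a cylindrical
$(s, z)$ finite-volume half-plane with cell volumes $2\pi s\,h^2$. Choices
that matter:

* **Masks** are assigned by the signed distance of cell centers to the two
  spheres; cell volumes are corrected by 5×5-subsampled fluid fractions and
  the fluid slivers of excluded boundary cells are credited to their
  cytoplasm neighbours, making the total discrete volume exact to ~0.03%
  without creating small-cell stability problems.
* **Advection** uses conservative upwind fluxes with a second-order
  MUSCL/minmod reconstruction, stepped in pseudo-time (CFL 0.5) to the
  steady state. Forward Euler limit-cycles with the second-order
  reconstruction; a Heun (RK2) step damps the limiter oscillation and
  converges to $\max|\dot\rho| < 10^{-6} k_a$ in a few hundred iterations.
* **Zero flux across masked faces** is the discrete counterpart of the
  no-inflow shell condition and of $\mathbf V \to 0$ on the aggregate; it
  conserves network mass exactly, so the steady-state global balance
  $\int k_a = k_d \int \rho$ holds to machine precision.
* **Pressure** is a variable-coefficient Poisson problem with pure Neumann
  data (harmonic-mean face friction), solved sparsely with one pinned cell
  and the gauge fixed to volume-weighted zero mean. The divergence
  tolerance is relative to the advective scale $\max|V|/h$.
* **Accuracy.** Against the closed-form spherically symmetric density
  profile (integrating factor solution of the 1D steady equation — an
  independent oracle), the volume-weighted L2 error is ~2.6% at $h = a/5$,
  ~1.4% at $a/8$ and <1% from about $a/12$; the residual is the intrinsic
  first-order boundary-cell error of a staircase mask. The oracle
  comparison in the acceptance suite therefore runs at $h = a/12.5$.

### 1.4 Exact scale invariance of the spring law

With proportional geometry ($a = c_a R$, $d = c_d R$, $h = a/5$) the
continuum problem is exactly scale invariant: $\mathbf V \propto \gamma R$,
$\rho$ dimensionless, so $F \propto \zeta_0 \eta \gamma R^4$ and the spring
constant $k = F/d \propto R^3$ — and the *discrete* problems for different
$R$ are the same lattice problem rescaled. The fitted log–log exponent is
therefore 3 to floating-point precision. This makes the scaling target
"exact by construction" — which is honest: the $R^3$ law is a property of
the model, and the simulation demonstrates rather than approximates it.
The uniform-density limit shows the same analytically:
$k \to \tfrac{4\pi}{3} \zeta_0 \eta \bar\rho^{\,\alpha} \gamma R^2 (R-a)$.

## 2. Recentering dynamics

`simulate_recentering()` mimics the release phase of a magnetic-pull
experiment. The initial condition is the centered steady-state density
displaced sideways together with the aggregate (cells vacated by the
aggregate start network-free). Each step advances the density *in real
time* by `dt` (the default co-evolving mode; a quasi-static variant
re-equilibrates fully), re-solves the cytosol flow, and moves the aggregate
overdamped: $\Delta d = (F/\Gamma_{agg})\,dt$. Co-evolution reproduces the
observed reorganisation lag — the force needs a few minutes to build up as
the network redistributes — before the speed peaks and then decays
concave-down in $d$. In the small-displacement, quasi-static limit the
trajectory matches $d(t) = d_0 e^{-kt/\Gamma}$ with $k$ from the
force-displacement fit (tested within 10%).

Interphase-like conditions are modelled *solely* by dividing $\gamma$ by
the contraction ratio (~3), with no other parameter change; the half-time
ratio comes out close to 3 because the spring is nearly proportional to
$\gamma$ (sub-proportionality from density redistribution makes it
slightly less).

## 3. The stochastic clutch model

The effective positioning model reduces the aggregate to its displacement
vector with three ingredients: deterministic centering at rate
$\lambda(R) = \lambda_0 (R/R_0)^2$ (spring $\propto R^3$, drag
$\propto a \propto R$), positional noise $D_{eff}$, and a two-state clutch
with $k_{on} = k_{on,0}/b$, $k_{off} = k_{off,0}\,b$ ($b$ = clearance to
the closest boundary, floored at $b_{min} = 0.5$ µm), constant engaged
speed $v$ toward the closest boundary point, and absorption at contact.

**3D state instead of a reflected radial coordinate.** The disengaged
dynamics are simulated as a full 3D Ornstein–Uhlenbeck process with exact
per-axis discretisation. A 1D radial simulation with reflection at zero
has stationary RMS $\sqrt{D/\lambda}$, not the 3D-consistent
$\sqrt{3D/\lambda}$ that the confined-walk statistics require; rather than
add the Bessel-type $2D/d$ drift (stiff near the origin), the package
keeps the vector state — which the squished ("pancake") geometry needs
anyway. Switching uses per-step exponential-clock probabilities
$1 - e^{-k\,dt}$ with an enforced validity bound
$dt \le 0.1/\max(k_{on}(b_{min}), k_{off}(R - a))$; at that bound an exact
event-driven sampler would agree to $O(dt)$, so none is provided.

**Defaults.** $v = 1$ µm/min and $D_{eff} = 0.32$ µm²/min are the measured
outward speed and positional diffusion. $\lambda_0 = 0.083$/min at $R_0 =
50$ µm is chosen so the disengaged stationary state reproduces the
measured confined fluctuations ($\lambda = 3 D_{eff}/R_c^2$ with $R_c =
3.4$ µm). Note the tension: deriving $\lambda$ from the hydrodynamic
spring instead (`clutch_lambda_from_spring()`) gives ~0.49/min at 50 µm —
the measured positional fluctuations are larger than the hydrodynamic
spring plus measured $D_{eff}$ would allow in a pure OU picture,
i.e. part of the observed jitter is not thermal-like noise in that spring.
The package defaults to the statistics-consistent value and exposes the
other. Finally $k_{on,0} = 2$ µm/min and $k_{off,0} = 0.003$/(µm·min) were
calibrated once against the qualitative experimental pattern — transition
zone in the low-to-mid 30s µm at 40 min, bimodal intermediate range,
polar fraction rising in time — and then frozen.

**What the model reproduces** (all under test): engagement frequency
decreasing with radius; polar fraction decreasing with size and
non-decreasing in time; metastability of the centered state; bimodal
intermediate-size outcomes; transition radius increasing when engagement
is strengthened ($k_{on}\times 4$, $k_{off}/4$ — the interface-nucleation
mimic); preferentially axial breaking in squished droplets, reducing to
the isotropic solid-angle split ($P(\text{axial}) = 1 - \cos 45^\circ$) in
the barely-squished limit. A deterministic mean-field variant (static
distance-dependent boundary force) collapses onto a single intermediate
attractor — no bimodality, no metastability — which is exactly the
argument for the *transient* nature of the interaction; it lives in the
test suite as a falsification harness, not in the API.

## 4. Track statistics

* **MSD** is time-averaged per track over all ordered pairs (lags from
  actual timestamps, so gaps simply remove pairs; pairs spanning gaps
  longer than two nominal intervals are excluded), then ensemble-averaged
  unweighted across tracks — mirroring the common particle-tracking
  convention. The fit is least squares of $\log \text{MSD}$ on $\log t$
  restricted to the stated window, parameterised as $6 D t^\alpha$.
  Whether tracks should be length-weighted is unspecified in the source
  analysis; unweighted was chosen and documented.
* **VACF** uses forward-difference velocities at a configurable interval,
  per-track normalisation $c(0) = 1$, ensemble mean *and* STD (never
  dropped).
* **Break detection** implements the A/B/C algorithm literally:
  qualification $\max(d/R) \ge 0.3$; A = last time $d \le 0.05R$; C =
  first time $d \ge 0.97\,d_{max}$; B = highest dot-product of consecutive
  velocity vectors in [A, C] (the original uses a 2 s interval available
  only in the high-rate movies; here the interval is a parameter defaulting
  to the native sampling); start = last negative radial velocity in
  [A, B], else A. One structural consequence, verified against generator
  truth: the recovered start cannot precede the crossing of the $0.05R$
  qualification band, so at $v = 1$ µm/min and $R = 40$ µm it sits
  systematically ~1–2 min after the true onset. Detection is idempotent on
  the event-cropped track within one sample interval.
* **Classification** thresholds $u = d/R$ at 0.4, smooths the binary
  states over droplet *diameter* with a Gaussian window of variance 5 µm²
  (SD ≈ 2.24 µm), and finds the polar/intermediate border where the
  cumulative mean of the curve first drops by 5% of its range (and the
  centered/intermediate border from the reverse cumulative mean of the
  complement). For a perfectly sharp step both borders collapse onto the
  transition and their order can invert by a fraction of the kernel width
  (each cumulative mean lags past the step); for any graded transition
  they order correctly around the intermediate zone. Both behaviours are
  tested. The construction is translation-equivariant in diameter.
* **Recentering alignment** sets $t = 0$ at the last outward-to-inward
  velocity sign change before the speed peak, falling back to the interior
  velocity minimum; monotone-velocity and zero-velocity tracks are
  excluded with warnings. The velocity-displacement ensemble is reported
  as *inward* speed vs displacement bin, which increases with $d$
  (concave-down), matching the recentering phenomenology.

## 5. Synthetic data: what a green test establishes

The generators reproduce the *statistical structure the analysis assumes*:
a stationary confined random walk (exact OU discretisation, so estimator
tests do not inherit integrator bias), an abrupt switch to a directed
outward run with $\text{MSD} = 6Dt + v^2t^2$ (log–log slope ≈ 1.5 over
0.5–10 min for the measured $v$ and $D$), absorption at the boundary, and
bimodal populations with a known transition radius. They deliberately do
**not** emulate: localisation error (available but off by default, as the
tracking error was not quantified), short-timescale temporal correlation
below the 0.5 min sampling (white-noise OU adopted), aggregate growth,
droplet drift, or any imaging artifact. A green analysis test therefore
establishes correctness of the estimator on the stated model class, not
performance on raw microscopy.

All generators require an explicit seed and are byte-reproducible;
truth metadata ride along as attributes and sidecar JSON, and tests
consume truth only in assertions.

## 6. Degenerate inputs and failure behaviour

Non-convergent relaxations abort with the residual history; singular
Darcy systems (all-zero density without a friction floor) are errors; the
clutch integrator rejects steps violating the switching-probability bound;
static tracks yield flagged `NA` fits rather than numbers; single-class
populations yield degenerate borders with a warning; per-point solver
failures in force-displacement scans produce `NA` rows and warnings so
partial curves remain usable; a recentering aggregate reaching the
boundary terminates with status `"escaped"` (the rare post-perturbation
polarisation).

## 7. Known limitations

* The network momentum balance is not solved; γ is prescribed. Questions
  about how contraction emerges are out of scope.
* The staircase mask limits the density solver to first-order boundary
  accuracy; the oracle error at $h = a/8$ is ~1.4%, reaching the 1% band
  only from $h \approx a/12$.
* The friction exponent α is calibrated to the sensitivity pattern, not
  derived from microstructure; anything in roughly [0.2, 0.5] is
  compatible with the qualitative constraints used.
* The clutch model is effective: no spatially resolved cortical actin, no
  feedback from clutch events into the PDE fields, and rate laws taken at
  face value ($k_{on} \propto 1/b$, $k_{off} \propto b$).
* Droplets are rigid spheres (or rigid oblate approximations in the
  pancake clutch geometry); no free-surface deformation.
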