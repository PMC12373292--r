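---
title: "The multicellular phase-field organoid model: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The multicellular phase-field organoid model: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`lumenoid` simulates an organoid as a collection of scalar phase fields on a
regular grid: one field $u_i(\mathbf r, t) \in [0,1]$ per cell
($i = 1,\dots,M$) and a single shared field $u_0$ for the lumen — the
fluid-filled cavity that cells enclose. A value near 1 marks the inside of
the cell (or lumen), near 0 the outside, and the diffuse front between the
two plateaus is the membrane, with width set by the interface coefficient
$D$: the equilibrium 1D profile is
$u(x) = \tfrac12\left(1 + \tanh\frac{x}{2\sqrt{2D}}\right)$, so the
interface tension is $\sqrt{D/2}$ and the profile integral
$\int u(1-u)\,dx = \sqrt{2D}$.

Every field relaxes down the gradient of a shared free energy, giving a
forced Allen–Cahn equation

$$\tau \partial_t u_i = D \nabla^2 u_i + u_i(1-u_i)\left(u_i - \tfrac12 + f_i\right),$$

where the force $f_i$ collects, for a cell: growth toward a target volume
$\alpha(V_\text{target} - V_i)$ with $V_i = \int h(u_i)\,d\mathbf r$ and
$h(x) = x^2(3-2x)$; volume exclusion $-\beta \sum_{j \ne i} h(u_j)$ against
all other cells *and* the lumen; and cell–cell adhesion
$\eta \nabla^2 \sum_{j \ne i} h(u_j) + \gamma \nabla^2 h(u_i)$, where the
$\gamma$ self-term is the cortical stabilizer of the adhesion term. The
lumen instead feels a constant osmotic drive opposed by exclusion from the
cells: $f_0 = \xi - \beta \sum_j h(u_j)$. The smoothed indicator $h$ is
chosen so that every energy term exerts a force proportional to $u(1-u)$,
acting on interfaces only.

Cell division is an event, not an emergent property: a cell divides when
its volume exceeds a threshold ($V_i > V_d$) *and* its age exceeds a
minimum inter-division time ($t_\text{cell} > t_d(1+\zeta)$, with $\zeta$ a
per-cell uniform draw in $[-0.1, 0.1]$ fixed at birth). Whichever
criterion is met last gates the event, so an isolated cell divides at
$\max(t_d(1+\zeta),\, t_\text{cell}(V_d))$. The division plane comes from
two "spindle pole" points relaxed under a shell attraction
$(\rho_0 - \rho_e e_\eta)\,u(1-u)\,(\mathbf r - \mathbf r_i)$ — integrated
over the half-space nearer each pole — balanced by a spring of stiffness
$\sigma$ between the poles; the adhesion energy density $e_\eta$ (negative
in contact zones) concentrates the pull toward cell–cell contacts. The
mother field is split by the smoothed half-plane indicator
$\chi = \tfrac12(1+\tanh(g/\epsilon))$ about the perpendicular bisector of
the pole axis, and a micro-lumen — a disk of fixed volume
$V_{L,\text{ini}} = 0.785$ — is carved at the pole midpoint ($u_0 := 1$,
daughters $:= 0$ inside). Because the lumen is one shared field,
micro-lumens that touch merge without any extra rule.

## Parameters

All quantities are dimensionless. The reference set (defaults of
`pf_params()`):

| parameter | value | role |
|---|---|---|
| $D$ | 0.001 | interface width/tension ($\sqrt{2D} \approx 0.045$) |
| $\alpha$ | 1 | volume restoring stiffness |
| $\beta$ | 1 | cell–cell / cell–lumen exclusion |
| $\gamma$ | 0.001 | cortical (self-interface) term |
| $\eta$ | 0.008 | cell–cell adhesion |
| $\xi$ | sweep, 0.27–0.40 | lumen (osmotic) pressure |
| $V_\text{target}$ | 3 (2D), 4 (3D) | target cell volume |
| $V_d$ | 2.9, or $\mathcal N(2.85, 0.025)$ | division volume threshold |
| $t_d$ | sweep, 0–300 | minimum inter-division time |
| $V_{L,\text{ini}}$ | 0.785 | micro-lumen seed volume |
| $\delta x$, $\delta t$ | 0.02, 0.01 | reference grid and step |
| $u = 0.2$ | — | analysis threshold (morphology only) |
| $\mu, \sigma$ | 0.001, 10 | spindle drag and spring |
| $\rho_0, \rho_e$ | 0.01, 1 | shell attraction and its contact bias |
| $\epsilon$ | 0.1 | division-plane smoothing width |

A caveat worth knowing: numerical stability of the adhesion term wants the
cortical coefficient to exceed the adhesion coefficient, yet the reference
set has $\eta = 0.008 > \gamma = 0.001$ (published parameter tables for
this model also list $\gamma = 0.01$, which would satisfy the rule). We keep the
reference methods values and warn instead of erroring. In practice the
consequence is visible only at fine resolution: at $\delta x = 0.02$,
cell–cell contact zones steepen their gradients and adhering cells can
inflate their measured volumes, while at the coarser $\delta x = 0.05$ used
throughout the test suite the effect is mild. Anyone running production
sweeps at fine resolution should consider $\gamma = 0.01$ explicitly.

The unit system (`unit_system()`, `dimensionalize()`) maps dimensionless
values to laboratory units through a reference length $L = 10\,\mu$m (a
cell radius), pressure $P = 1$ kPa (epithelial traction) and speed
$v = 0.6\,\mu$m/min (migration), giving $f_0 = PL^2 = 100$ nN,
$t_0 = L/v = 16.7$ min, and tension scale $\Gamma = f_0/L$. Under this map
$\xi = 0.3$ is 300 Pa, $\eta = 0.008$ is 80 Pa·$\mu$m, $t_d = 100$ is about
28 h, and a unit water permeability is 36 $\mu$m/(h·kPa).

## Numerics

The integrator is first-order explicit Euler with a synchronous update
(all forces from the pre-step state), second-order central differences,
and no-flux (mirror ghost) boundaries; boundary conditions are inert for
reported behaviour because runs stop when the organoid reaches a margin of
the domain. The diffusive stability bound
$\delta t \le s\,\delta x^2 / (2 d D)$ is enforced with safety factor
$s = 0.5$. After each step fields are clamped to
$[-10^{-6}, 1 + 10^{-6}]$; non-finite values abort the run and are
recorded as a blow-up. The compiled stepper (`step_block()`) is verified
to machine precision against a pure-R reference (`euler_step()`) on every
test run; all per-cell fields are stored on the full domain. The
simulation clock advances in units of $\delta t$; division eligibility is
checked every 10 steps by default, so division times are resolved to
0.4 time units in the scaled geometry — well below the noise scale
$t_d \zeta$ for any $t_d \gtrsim 4$.

Spindle poles are relaxed by explicit pseudo-time iteration with step
$0.5\,\mu/\sigma$ (which makes the pole-separation mode an exact solve per
iteration), convergence when both displacements fall below $10^{-8}$, and
a $10^5$ iteration cap. Poles are initialized at the cell's centre of mass
$\pm 2\delta x$ along a seeded random direction; the converged axis is set
by the force field, and the steady separation is $O(|F|/\sigma) \sim
10^{-4}$ — tiny, but only the axis direction and midpoint enter the split.
Simultaneous divisions are processed in ascending cell id against fields
frozen once per batch, with $e_\eta$ computed once; equidistant points in
the half-space integral go to the first pole.

## Morphology and classification

The analysis layer thresholds the lumen field at $u = 0.2$ (never used by
the dynamics). Connected components use face connectivity (4 in 2D, 6 in
3D). Two measures coexist deliberately:

* **volumes** are $h$-integrals restricted to the component mask — these
  feed lumen occupancy $A_l/A_o$ (organoid volume includes the lumen) and
  the stable-lumen cutoff (a component is a stable lumen when its volume
  is at least $2 V_{L,\text{ini}}$);
* **perimeter and enclosed area** come from the same sub-grid iso-contour
  at the threshold (marching-squares style, via `contourLines`), because
  sphericity $2\sqrt{\pi A_{sl}}/\ell_{sl}$ only converges to 1 for a
  circle when both factors are measured on the same curve. Pixel-edge
  counting would bias perimeters by up to $4/\pi$; mixing the $h$-area
  with the contour perimeter biases a circle about 4% low at the default
  interface width.

For multiple stable lumens, areas and perimeters are summed before
combining, so sphericity penalizes fragmentation. The lumen index
$\ell_{sl}/(aN)$ uses a typical apical width $a = 1.6$ in 2D ($0.05$ with
the 3D surface measure $S_l = \int u(1-u)\,d\mathbf r$, which equals
$\sqrt{2D}$ per unit of true interface area). The occupancy trend is the
least-squares slope over the trailing 200 time units with a flat dead-band
of $10^{-5}$ per unit time; end-of-run indices are means over the trailing
50 units. Phenotypes follow the decision table: ruptured short-circuits;
no stable lumen $\to$ multilayer no-stable-lumen; one stable lumen with
increasing occupancy splits star shape vs monolayer cyst at sphericity
0.6; several stable lumens split branched vs multilayer multi-lumen on the
trend sign. Flat trends are grouped with decreasing ones — a lumen that
fails to outpace proliferation behaves like the decreasing classes — and
the dead-band width is ours, not a published value. Rupture is detected
when a supra-threshold lumen component reaches within 2 grid cells of the
boundary or when more than $V_{L,\text{ini}}$ of lumen lies outside the
convex hull of the cell mask; ruptured runs are conventionally excluded from
downstream analysis and no standard criterion exists, so this
operationalization is ours.

## Scaled study geometry

The full-size setup (domain $40 \times 40$ at $\delta x = 0.02$, i.e.
$2000^2$ nodes, runs to $t \sim 10^3$) is supported but not exercised by
the test suite. Tests and the acceptance script run on reduced domains
(6–14 length units) at $\delta x = 0.05$, $\delta t = 0.04$, which
resolves the interface with $\sim 4$ nodes and keeps every oracle within
its stated tolerance (profile sup-norm $< 10^{-3}$, isolated-cell volume
within 2%, droplet growth/shrinkage on both sides of the critical radius
$R_c = \sqrt{D/2}/\xi$). Phase-boundary positions shift under scaling — the same sensitivity is
known for initial cell numbers — so scaled
full runs are used for qualitative structure only: at $t_d = 40$ on a
$10 \times 10$ domain, $\xi \le 0.44$ yields multilayer no-stable-lumen
outcomes while $\xi = 0.55$ yields a monolayer cyst that terminates at the
boundary.

## The reduced lumen theory and the pressure fit

For an isolated circular lumen the field dynamics reduce to
$\dot V_0 = (k/6)(\xi - \sqrt{D/2}/R)$: the osmotic drive against the
Laplace pressure of the bare interface, with unstable fixed point at
$R_c$. Identifying the kinetic constant with a water permeability gives
the enclosed-lumen growth law
$\dot V_0 = (\lambda_w/6)\,A_\text{apical}\,(\xi - \Delta p)$, with
$A_\text{apical}$ the measured lumen perimeter and $\Delta p$ the
hydrostatic pressure sustained by the cell layer.

`fit_hydrostatic_pressure()` extracts $\Delta p$ per $\xi$ and regresses
it on $\xi$ through the origin. Two estimators are provided. The default
fits the growth as a function of the measured radius — $\Delta p = T/R$
makes $6\dot V_0/\ell$ linear in $1/R$, estimating $(\lambda_w, T)$
jointly — but this is reliable only when growth actually varies with
curvature; on layer-limited trajectories (front speed nearly constant) it
is ill-conditioned. The reported number therefore uses the second
estimator: $\lambda_w$ is first calibrated on an isolated droplet, where
the counter-pressure is known exactly; the calibration lands within 1% of
the continuum front-mobility value $6\sqrt{2D}$ ($\approx 0.268$ at the
default $D$, for $\tau = 1$). With $\lambda_w$ fixed, $\Delta p$ is the
least-squares constant over the recording window. We chose the calibrated
mobility over the $1/\tau$ bookkeeping convention ($\lambda_w = 1$)
because the latter folds the finite front mobility into $\Delta p$ —
under it even a resistance-free layer reports
$\Delta p \ge (1 - 6\sqrt{2D}/6 \cdot 6)\,\xi \approx 0.73\,\xi$ — whereas
the calibrated value separates layer mechanics from interface kinetics.

The measurement protocol (also used by `scripts/acceptance.R`): a ring of
12 annular-sector cells at half the division volume — the composition of a
layer immediately after a division wave, which is what a proliferating
monolayer continually returns to — enclosing a lumen of radius 2.2 on a
14-unit domain; a 10-unit transient is discarded and volume and perimeter
of the labeled stable lumen are recorded for 80 units at cadence 2, for
$\xi \in \{0.28, 0.31, 0.34, 0.37, 0.40\}$. The zero-intercept slope
comes out near 0.66 with a standard error of about 0.04, against the
published proportionality of 0.7.

## The monolayer balance

A monolayer cyst persists when the lumen perimeter grows at the same rate
as $a N$. The test fixture for this balance is an established cyst: a ring
of 9 cells (so the initial apical width equals $a$) whose birth times are
staggered uniformly over one division period — a synchronized ring
divides as a wave and transiently multilayers, which is an artifact of
symmetric initial ages, not of the balance mechanism. At $\xi = 0.34$ and
$t_d = 250$ (chosen so the division period matches the perimeter growth
rate) cells divide one at a time, micro-lumens merge into the central
lumen, and the 50-unit running mean of the lumen index stays within
$[0.8, 1.2]$ for the whole 150-unit window while the instantaneous index
briefly overshoots during merges.

## What the synthetic fixtures do and do not show

The fixture generators produce tanh-profile single cells, ring cysts, and
geometric masks — all idealized, noise-free initial states. Passing tests
on them demonstrates that the discretized operators, the division
bookkeeping, and the index definitions are correct, and that the model's
characteristic behaviours (volume homeostasis, critical-radius growth,
monolayer balance, phenotype separation along $\xi$) appear in scaled
geometry. They do not demonstrate quantitative phase-boundary positions of
the full-size sweeps, anything about real organoid images (no imaging
noise, no segmentation errors enter the fixtures), or 3D growth beyond
small relaxation tests.

## Known limitations

* The default $\gamma < \eta$ regime is numerically delicate at fine
  resolution (see Parameters).
* Checkpoints are R serialization files, not a language-neutral container;
  TIFF export covers visual inspection.
* The joint $(\lambda_w, T)$ fit degenerates on layer-limited growth; use
  the calibrated-mobility estimator there.
* 3D runs are supported by the stepper and morphology layers but have not
  been validated against full-size 3D sweeps.
* Cells never die or extrude by rule; only the dynamics can remove
  material, so the cell count is exactly the division count plus the
  initial cells.
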