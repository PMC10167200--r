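---
title: "Parametric aortic valves as resistive immersed surfaces: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parametric aortic valves as resistive immersed surfaces: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`riisvalve` builds open aortic-valve geometries from about fifteen scalar
parameters per leaflet, converts them into a volumetric resistive penalty
field, and simulates transvalvular systolic flow in a cylindrical domain.
This vignette records the mathematical models, the numerical choices, and
the boundaries of what the package's tests do and do not demonstrate.

# The parametric leaflet model

Each leaflet is intra-symmetric (two mirrored halves) but the three leaflets
of a valve are independent, so healthy and stenotic valves alike can be
represented. One half leaflet is bounded by four curves:

* **Leaflet curve** (free edge, plane $z = l_h$): $f(y) = l_{ri} + \alpha
  y^{l_p}$ with $\alpha = (l_{ro}\cos l_a - l_{ri}) / (l_{ro}\sin l_a)^{l_p}$.
  The three defining conditions are $f(0) = l_{ri}$, $f'(0) = 0$ (smooth
  mirror joint), and passage through the commissure point on the outer
  circle. The power $l_p > 1$ controls how long the edge hugs the inner
  circle before sweeping outward; large powers give the flattened, rounded
  orifices of calcified valves.
* **Bending curve** (plane $z = b_h$): the same construction with
  $b_{ro}, b_{ri}, b_a, b_p$; it controls how the leaflet belly folds
  between annulus and free edge.
* **Sinus curve**: a quadratic Bezier from the annulus attachment
  $P_0 = (r_r\cos l_a, r_r\sin l_a, 0)$ to the commissure
  $P_2 = (l_{ro}\cos l_a, l_{ro}\sin l_a, l_h)$, with $P_1$ solved so the
  curve passes through the bending-plane outer point
  $(b_{ro}\cos b_a, b_{ro}\sin b_a, b_h)$ at parameter $s = b_h / l_h$. It
  stands in for the sinus and interleaflet anatomy, which the model
  deliberately does not resolve.
* **Symmetry curve**: a cubic Bezier in the plane $y = 0$ from
  $Q_0 = (r_r, 0, 0)$ to $Q_3 = (l_{ri}, 0, l_h)$; $Q_1$ encodes the
  departure tangent through two weights (default $-0.2$ each) and $Q_2$ is
  solved from interpolation of the bending point $(b_{ri}, 0, b_h)$.

On the sinus side the interpolation target is the *outer* bending point
$(b_{ro}\cos b_a, \dots)$: this is the only choice for which the four
boundary curves meet at well-defined corners, and the package asserts those
corner identities at construction time.

## Surfaces

The two analytic curves are approximated by cubic Beziers whose inner
control points follow finite-difference tangent estimates at the two ends,
offset by the calibration weights $t_0, t_3 \in (0,1)$ interpreted as
*fractions of the lateral extent* $y_{max}$ (the finite-difference step is
$10^{-6} l_{ro}$, relative and therefore scale-invariant). The fractional
interpretation keeps the weights dimensionless: absolute millimetre offsets
confined to $(0,1)$ would pin the inner control points against the endpoints
of a centimetre-scale curve and reduce the cubic to a near-chord, which no
calibration could rescue for high-power edges. At $t_0 = t_3 = 1/3$ the
placement coincides with cubic Hermite interpolation and reproduces a
power-2 edge exactly; the defaults are 0.3, and `calibrate_edge_weights()`
grid-searches the pair per parameter set (the synthetic cohorts calibrate
each leaflet automatically, holding the dense-sampled deviation of the
fixtures below $0.05\, l_{ro}$). The sinus
and symmetry curves are split at the bending plane with De Casteljau's
algorithm — an exact operation, tested against direct reparametrized
evaluation at $10^{-12}$ mm. Each half leaflet is then two Coons patches
(bilinear blend of four boundary curves minus the corner interpolant): a top
patch between bending and leaflet curves and a bottom patch between the
annulus boundary and the bending curve. The bottom patch's fourth boundary is
not specified by the leaflet model itself; the package uses the circular
annulus arc of radius $r_r$ from angle $0$ to $l_a$, with a degenerate-point
alternative available. Top-patch side curves are oriented with $v = 0$ on the
bending plane so every corner identity holds exactly.

A full valve is six patch functions (top and bottom per leaflet); the
mirrored halves are realized by reflecting the evaluation point across each
leaflet's local symmetry plane, which is the same surface without doubling
the patch count. Inter-leaflet closure is validated softly: half-angle sums
away from $360°$ and commissure gaps beyond a configurable tolerance produce
warnings, not errors, since deliberately gapped pathological fits are a
legitimate use.

# The resistive field

The valve enters the flow problem as a scalar nodal function $\gamma$: for
each mesh node the minimum distance $d$ to the six patches (and their
mirrors) is found by box-constrained local minimization over the closed
parameter square, started from the best point of a coarse $5\times5$
multistart grid per patch — the multistart guards against the local minima
that high-power leaflet curves induce. Then

$$\gamma(N) = \begin{cases} C & d \le \varepsilon \\ 0 & \text{otherwise},
\end{cases} \qquad \varepsilon = \max(h_{phys}/2,\; 0.75\, h_{max}),$$

with $C = 10^8$ and the threshold inclusive at equality. The
$0.75\,h_{max}$ rule keeps the one-layer-thick leaflet free of holes; the
physiological floor $h_{phys}/2$ stops the layer collapsing under mesh
refinement. A dense-sample prefilter (41×41 per patch) classifies nodes that
are provably inside ($d_{sample} \le \varepsilon$) or provably outside
($d_{sample} > \varepsilon + \delta$, $\delta$ the maximal sample spacing)
without running the optimizer; only the ambiguous shell is polished. The
prefilter cannot change any value, only skip decided nodes, and nodewise
results are independent of evaluation order.

# Flow model and discretization

Incompressible Navier–Stokes with the penalty term $\gamma \mathbf{u}$ in
the momentum equation, density 1060 kg/m³ and viscosity 3.5 mPa·s (standard
blood values, configurable), from rest to peak systole. The inflow is a
parabolic profile with a half-sine envelope $\sin(\pi t / T)$ over the
systolic interval $T = 0.4$ s, peaking at $T_{end} = 0.2$ s; its amplitude
realizes a peak inlet Reynolds number (diameter-based, on the profile
maximum) of 1200. The outlet is a natural do-nothing boundary augmented with
backflow stabilization penalizing the negative part of $\mathbf{u}\cdot
\mathbf{n}$ (coefficient 0.5); the lateral wall is no-slip.

Space: P1-bubble/P1 (MINI) mixed elements on tetrahedra. The bubble is
treated quasi-statically and condensed element-wise: it enriches the
generalized-Stokes block (mass/$\Delta t$ + viscous + $\gamma$) and its
elimination yields the SPD pressure-gradient stabilization
$\tau_e \nabla q\cdot\nabla p$ with
$\tau_e = (\int b)^2 / [(\rho/\Delta t + \bar\gamma)\int b^2 + \mu \int
|\nabla b|^2]$, all integrals exact on each element. Convection and the
Temam term $\frac{\rho}{2}(\nabla\cdot\mathbf{u})\mathbf{u}\cdot\mathbf{v}$
are assembled on the P1 component with the previous-step advecting velocity
(semi-implicit; optional Picard sweeps). Because the desk-scale meshes run
at cell Péclet numbers of several hundred, the convection operator also
carries a streamline-upwind diffusion
$\rho\,\tau_e (\mathbf{w}\cdot\nabla\varphi_i)(\mathbf{w}\cdot\nabla
\varphi_j)$ with $\tau_e = h_e / (2|\mathbf{w}|)$, which suppresses
node-to-node oscillations without smearing cross-stream gradients; it
vanishes with the mesh size. Time: backward Euler, $\Delta t = 2.5$ ms at
the fine preset, 10 ms in the desk preset.

The linear saddle system is solved monolithically per step by BiCGSTAB with
a block-triangular preconditioner: a sparse LU of the velocity operator and
a Cholesky factorization of the approximate pressure Schur complement
(bubble stabilization plus $B^T \mathrm{diag}(A)^{-1} B$). The
preconditioner is frozen across steps and refreshed when convection drift
slows convergence (more than 40 iterations) or on solver stagnation; the
relative residual tolerance is $10^{-8}$. Taking $q = 1$ in the stabilized
continuity equation shows the stabilization row-sums vanish, so discrete
global mass balance holds to solver tolerance — the penalty removes
momentum, not mass.

## Domain and mesh

The domain is a cylinder of radius $\max_i l_{ro,i}$ spanning $[-2 l_h,
+6 l_h]$: two leaflet heights of entry length and six of jet development,
both package choices. The mesh is a triangulated-disk extrusion with graded
axial layers (fine spacing in a band covering the valve with a two-cell
margin, coarse elsewhere) and prisms split into tetrahedra by an index-based
diagonal rule that guarantees conformity. In-plane resolution follows the
fine size everywhere; only axial spacing is graded — a deliberate
simplification that keeps the extrusion structure available for exact
plane-interpolated pressure averages. The fine preset uses 0.5/0.75 mm; the
desk preset (used by the tests and the acceptance script) scales them to
1.5/2.25 mm so a full run fits on one CPU in minutes: about 14k nodes and
74k cells for a 14 mm valve.

## Diagnostics

$v_{max}(t)$ is the whole-domain peak nodal velocity magnitude, analogous to
the continuous-wave Doppler peak. $\Delta P(t)$ is the area-averaged
pressure one leaflet height upstream minus three heights downstream
(configurable; pressures are interpolated along the extrusion columns, exact
for fields linear in $z$). The Bernoulli comparison fits $\Delta P = a
v^2 + b v + c$ by least squares over a cohort of runs and reports each
point's ratio $\Delta P / v_{max}^2$ against the clinical constant 4.

# What the synthetic cohort shows — and what it does not

No patient parameter tables are published for this class of model, so the
package generates cohorts itself: a shared anatomy (aortic radius 14 mm,
annulus 12 mm, leaflet height 10 mm, bending at half height) with the
orifice ratio $l_{ri}/l_{ro}$ stepping 0.55 / 0.42 / 0.28 / 0.15 and curve
powers rising 2→5 from healthy to severe; optional seeded 5% per-leaflet
jitter (half-angle jitter redistributed to keep the three leaflets closing)
emulates anatomical asymmetry. These ranges are grounded in normal adult
aortic dimensions and are package choices, not measured data.

Consequently the simulations demonstrate *mechanisms and trends*: orifice
area falls with severity, the jet forms downstream of the orifice, and the
transvalvular drop rises monotonically with severity. They do not reproduce
any specific patient, and desk resolution imposes two visible scale
artifacts worth understanding. First, the resistive layer (half-thickness
$\varepsilon = 0.75\,h_{coarse} = 1.69$ mm at desk scale) occupies a large
fraction of a severely stenotic orifice: once $2\varepsilon$ exceeds the
orifice core diameter the valve *chokes* — the pressure drop keeps climbing
(it is then dominated by seepage through the penalized layer) while the jet
can no longer accelerate, so peak velocity is monotone in severity only
while the orifice stays resolved. Second, the default pressure planes sit
one leaflet height upstream and three downstream, where part of the dynamic
pressure has been recovered; for moderately open valves this *pressure
recovery* pulls the net gradient below the vena-contracta-referenced
estimate $4 v_{max}^2$, a well-known clinical effect. Layer-dominated
(severe-grade) valves, the population the gradient–velocity relation is
clinically about, sit far above the Bernoulli parabola at any plane choice;
the package's Bernoulli cohort therefore consists of severe-grade valves
with varying anatomical asymmetry, and the check is one-sided by design. Penetration through the penalized layer
scales like $|\nabla p| / C$; with $C = 10^8$ this keeps leaflet-layer
velocities orders of magnitude below the jet but not below fractions of the
*inlet* peak when the transvalvular gradient is large, which is why the
package's penalization-effectiveness test drives a full-section slab with a
prescribed pressure head and compares against the open-tube Poiseuille peak
velocity under the same head — a setup where suppression below $10^{-3}$ of
the reference is a meaningful, mass-consistent statement. (A slab spanning
the whole cross-section with a *prescribed inlet flux* cannot show small
velocities: continuity forces the flux through the slab.)

# Numerical choices and degenerate inputs

* Curve powers must exceed 1 so the finite-difference tangents at the
  symmetry line are well defined; $b_h \in (0, l_h)$ strictly, so the
  De Casteljau splits at $s = b_h/l_h$ never degenerate.
* The distance optimizer works on the closed box $[0,1]^2$ because nearest
  points frequently lie on patch boundaries; optimizer failures fall back to
  a refined grid with a warning.
* $\gamma$ is exactly two-valued; the support is checked for connectivity
  per valve (a union-find over support-restricted mesh edges) and an empty
  or fragmented support warns rather than errors.
* Backward Euler plus the Temam term keeps the coarse desk runs stable at
  convective CFL numbers well above 1; the price is numerical dissipation,
  accepted for trend-level results.
* All file formats are plain (binary STL, legacy ASCII VTK with `%.17g`
  precision so nodal fields round-trip bitwise).

# Known limitations

Fixed open valve only — no fluid–structure interaction, opening/closing
dynamics, or coaptation. No sinuses of Valsalva or anatomical aorta; the
cylindrical wall exaggerates jet impingement. No turbulence model at
Re 1200. In-plane mesh resolution is not graded. The CT parameter-extraction
protocol that would make runs subject-specific is out of scope; the fixture
generator stands in for it and is clearly labelled synthetic.
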