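---
title: "Stationary action, caustics, and the stability of torsional folding motions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stationary action, caustics, and the stability of torsional folding motions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(causticfold)
```

## The model

Protein folding is treated as classical motion in the space of backbone
dihedral angles. A `TorsionChain` has $n$ angles $\theta_i$ with diagonal
rotational inertias $I_i$ and a torsional potential $V$; its Lagrangian is

$$L = T - V = \tfrac12 \sum_i I_i \dot\theta_i^2 - V(\theta, t),$$

and realized motions make the action $S = \int_{t_0}^{t_1} L\,dt$
stationary, i.e. satisfy the Euler--Lagrange equations
$I_i\ddot\theta_i = -\partial V/\partial\theta_i$. Angles live on the real
line in radians (no $2\pi$ identification: the framework treats dihedral
space as a vector space), and energies default to units of $k_BT$.

Two deliberate conventions, both exposed rather than silently chosen:

* **Harmonic springs evaluate $V = k\theta^2$** — the convention printed in
  the folding-simulation literature this package models — with the textbook
  $\tfrac12 k\theta^2$ behind the explicit flag `half_k = TRUE`. Every test
  states which convention it uses.
* **The cusp potential is $V = \tfrac14\theta^4 + \tfrac12 a\theta^2 +
  b\theta$** (linear control term), because only the linear term yields the
  two-control-parameter cusp unfolding. A variant with a constant offset
  $+b$ instead of $+b\theta$ circulates in the source material; constant
  offsets do not affect criticality, and that variant is available behind
  `cusp_potential(..., linear = FALSE)`.

The one-angle cusp chain is the torsional analogue of the Zeeman
catastrophe machine: an asymmetric angular spring (`asymmetric_spring()`,
a $C^1$-matched piecewise quadratic — the force to turn a dihedral angle
depends on the direction of turning) whose static balance develops exactly
this quartic action.

The kinetic-energy metric of a real dihedral chain is not specified by the
theory; diagonal inertia is this package's choice, and cross-terms in the
*potential* are supported through `coupled_potential()`.

## Dynamics

`integrate_trajectory()` uses velocity Verlet (symplectic, order 2) on a
fixed uniform grid; RK4 is available and is selected automatically for
time-scheduled potentials. Two design points matter:

* **Symplecticity**: caustic timing is a phase measurement, and Verlet's
  energy error is bounded (oscillatory, no secular drift), so phases stay
  honest over long runs. At step $h = 10^{-3}$ the relative energy error on
  the unit-frequency harmonic test stays below $10^{-6}$; the suite also
  integrates $10^3$ periods at $h = 10^{-2}$ and checks the error envelope
  does not grow.
* **Fixed step**: trajectory grids must align across a family and with the
  second-variation discretization, so there is no adaptive stepping.

`shoot_family()` launches one trajectory per value of a scalar parameter
$u$ indexing a curve of initial states (fixed position with velocity $u$,
or vice versa). Scalar $u$ only: surfaces of start states are out of scope
in this version.

## Second variation and conjugate points

For a stationary arc $x_0(t)$ and a variation $\xi(t)$ with
$\xi(t_0) = \xi(t_1) = 0$,

$$\frac{d^2S}{d\epsilon^2}(0) =
  \int_{t_0}^{t_1}\left[\dot\xi^\top M \dot\xi
  - \xi^\top \mathrm{Hess}\,V(x_0(t))\,\xi\right] dt .$$

In one angle this is the familiar $\int [m\dot\xi^2 - \xi^2 V'']\,dt$; in
several angles the curvature term is the full Hessian quadratic form,
cross-terms included. `second_variation_form()` discretizes it with
piecewise-linear finite elements on the trajectory grid: the element
stiffness integrals are exact, the potential term is mass-lumped
(trapezoid), which makes the matrix block-tridiagonal and the quadratic
form identical to direct quadrature of the integrand for piecewise-linear
$\xi$. Dividing the eigenvalues by the lumped weight $h$ recovers the
Sturm–Liouville spectrum of the Jacobi operator (verified against
$(j\pi/T)^2 - \omega^2$ in the tests).

A **conjugate point** is where the second variation of the sub-arc first
loses positivity as the movable endpoint slides forward; beyond it the arc
is a saddle of the action, not a minimum. Two independent routes are
implemented and cross-checked on every test system:

* `find_conjugate_points()` tracks the negative-eigenvalue count (Morse
  index) of the restricted form. On a uniform grid the restricted form is a
  leading principal submatrix of the full one, so one $LDL^\top$ pivot
  sweep yields the index of every truncation in $O(N)$; index jumps are
  refined by bisection on a truncation with a partial final element, to
  tolerance $\min(h/100, h^2)$ — at least the advertised $h/100$, and
  tight enough that refinement never caps the discretization's second-order
  convergence of $t^*(h)$.
* `jacobi_conjugate_points()` integrates the Jacobi equation
  $M\ddot\xi = -\mathrm{Hess}V(x_0(t))\,\xi$ with $\xi(t_0)=0$,
  $\dot\xi(t_0)=I$ and reports zeros of $\det\xi(t)$; multiplicity comes
  from the rank drop.

An eigenvalue counts as zero below $10^{-8}\,\max(m)/h^2$ (the stiffness
scale), which suppresses round-off caustics. Trajectories with
discontinuous $V''$ (asymmetric springs) evaluate the Hessian one-sidedly
at the rest angle; accuracy degrades to $O(h)$ at crossings, a documented
trade-off.

## Family action surfaces and caustics

For a family starting along a curve parameterized by $u$, the action
accumulated to time $t$ is tabulated per member and per grid time,
$S(u, t)$, with $u$-derivatives by centered differences
(`family_action_surface()`); closed-form families over explicit control
grids use the same container (`analytic_action_surface()`). A caustic point
satisfies $\partial S/\partial u = 0$ and
$\partial^2 S/\partial u^2 = 0$ simultaneously. `detect_caustic()` scans
each column for stationary points and reports three event types: a
stationary point whose curvature changes sign between adjacent columns
(interpolated), a change in the stationary-point count (a fold — two roots
merge), and fully degenerate columns. Fold events are refined by a local
quadratic fit of $S_u$ around the merging pair: the fit's discriminant
crosses zero exactly at the fold, giving sub-cell localization (on the
analytic cusp family the detected points satisfy
$|4x_1^3 + 27x_2^2| < 2\times10^{-3}$ on the default test grid, two orders
below the cell-size bound). A caustic whose spatial extent collapses below
two grid cells is tagged a **focus**. Default tolerances —
`tol_first = 1e-6 * range(S)`, `tol_second = 1e-4 * median|S_uu|` — are
deliberately configurable because "near vanishing" is grid-dependent; the
tests pass tolerances matched to their stated grids.

Two geometric cross-checks accompany the surface test:
`envelope_points()` finds tangencies of neighboring members (zeros of
$\partial x/\partial u$, or of the cross product
$\partial x/\partial u \times \partial x/\partial t$ for two angles),
scanning both along $u$ (fold envelopes, e.g. the safety parabola of a
projectile-like two-angle family) and along $t$ (focus pinches); and
`hessian_determinant_scan()` implements the higher-dimensional caustic
criterion $\det \mathrm{Hess}\,S = 0$ on arbitrary action fields, reducing
exactly to the $S_{uu}$ test in one dimension.

**A sign-direction caveat.** For the velocity-parameterized harmonic focus
family the fixed-time slice has the closed form
$S_{uu}(u,t) = \sin t\cos t$: *negative* just before the focus at
$t = \pi$ and positive after. The path-space second variation meanwhile
goes positive $\to$ indefinite, as the conjugate-point scan confirms. The
two orderings are different objects; `saddle_check_beyond()` therefore
confirms a caustic when the definiteness pattern of $S$ in $u$ *changes*
across it (a curvature direction flips sign), without prescribing the
direction of the flip. Points too close to the scanned boundary report
`"unconfirmable"` rather than erroring.

## Catastrophe theory

`normal_form_registry()` holds Thom's seven elementary germs — fold $s^3$,
cusp $s^4$, swallowtail $s^5$, butterfly $s^6$, hyperbolic umbilic
$s_1^3+s_2^3$, elliptic umbilic $s_1^3-3s_1s_2^2$, parabolic umbilic
$s_1^2s_2+s_2^4$ — with control dimensions $(1,2,3,4,3,3,4)$ and standard
universal unfoldings. The registry takes the seven-form statement as
canonical; the bound of "up to five control parameters" quoted in parts of
the catastrophe-optics literature is consistent with (and looser than) the
maximum of four needed here, and the acceptance suite checks the $\le 5$
bound as stated.

`classify_germ()` fits a degree-$\le 6$ polynomial jet by least squares
(degree 6 suffices: the butterfly is $s^6$, the parabolic umbilic degree 4
in two variables), decides corank from the Hessian eigenvalues (zero below
$10^{-6}$ of the curvature scale $\max(|\lambda|_{\max}, f_{\max}/w^2)$ on
a window of radius $w$ — the floor keeps noise-level quadratic
coefficients of a degenerate germ from reading as full rank), and then:
corank 0 is Morse; corank 1 classifies by the leading degree of the jet
restricted to the null direction; corank 2 by the real-factor structure of
the cubic part via the binary-cubic discriminant (three real factors:
elliptic; one: hyperbolic; repeated, with a quartic term: parabolic).
Residuals above threshold return `"unclassified"` — right-equivalence up to
an arbitrary diffeomorphism is not numerically decidable, and no attempt is
made to fake it.

**Structural stability** is operationalized the same way: a perturbation
"preserves the shape" when the count and Morse indices of critical points
in a window are unchanged, enumerated by dense derivative sign-scanning
plus root polishing. `perturbation_stability_test()` draws random
polynomials with degrees strictly above the germ degree (lower degrees
probe unfolding terms, not the stability claim — hence the guard) and
coefficients uniform in $\pm$`amplitude`. For a fixed seed the draws are
unit polynomials scaled by the amplitude, so a preserved-fraction ladder
compares the same perturbation shapes — this makes the monotonicity
property well-defined. The test covers one-state-variable forms only;
dense critical-point enumeration in two state variables was judged out of
proportion to its use here and errors clearly. There is no general rule
for how large a perturbation the local picture tolerates; the
large-amplitude arm of the test documents the breakdown empirically
rather than asserting a threshold.

**Boltzmann moments**: $\langle\theta^k\rangle$ under
$e^{-V/k_BT}$ by adaptive quadrature on a window grown until the weight at
its ends drops below $10^{-16}$ of its maximum; a weight maximized at the
window boundary marks the potential non-confining (integrability error).
The closed form for the pure quartic,
$\langle\theta^2\rangle = \sqrt{4k_BT}\,\Gamma(3/4)/\Gamma(1/4)$, was
verified by independent quadrature before being frozen into the tests.
`recover_cusp_controls()` inverts the first three moments over $(a,b)$ by
Nelder–Mead least squares; the quartic term keeps the forward map defined
for any controls.

## Kinetics

The folding arm of two-state kinetics is
$\mathrm{rate} = \gamma\,e^{-\Delta G^\dagger/k_BT}$ with
$\Delta G^\dagger = \Delta G_0^\dagger\,C$ under denaturant, so the
chevron's folding arm is exactly linear in $C$. Only this arm is modeled:
the V-shape needs an unfolding rate the framework does not supply. For
contact order, the source text can be read two ways (the prefactor
"increases with distance along the chain", yet folding time is
"proportional to contact order"); the implementation follows the
proportionality claim — collision time $\propto$ contact order, effective
prefactor `gamma_scale / CO^exponent` with the exponent exposed — and
records the ambiguity here rather than hiding it.

## The synthetic world, and what a green test establishes

`generate_fixture()` writes seeded, byte-reproducible fixtures whose
manifests embed their analytic ground truth (focus time $\pi$, fold
discriminant $4x_1^3+27x_2^2=0$, cusp critical points $-1,0,1$, exact
moments), so tests never hard-code the same number twice. Defaults are the
stated conditions of the framework where it states them (harmonic focus
family: fixed start, velocities $u\in[-2,2]$; Zeeman toy: $a=-1$, $b=0$;
stability: degrees 5–8, amplitude $10^{-3}$, 200 trials, seed 42) and
field-plausible choices elsewhere (grids sized so that detection
tolerances are a few cells; 1% multiplicative noise for moment recovery,
the scale of a careful equilibrium estimate).

The generator emulates one- and two-angle integrable toy systems with
known caustic structure. It does **not** emulate: rough multi-well
landscapes, solvent damping or noise (dissipation is explicitly outside
the conservative action formalism used here), hundreds of coupled angles,
or any sequence-to-parameter mapping — the theory itself leaves that
unresolved. A green suite therefore establishes that the machinery finds
caustics where variational analysis says they must be, on systems where
that answer is provable — not that real proteins have them.

## Numerical choices, in one place

| quantity | default | why |
|---|---|---|
| integrator step | user-set; $10^{-3}$ for drift tests | $(\omega h)^2$ energy-error scale below $10^{-6}$ |
| stationarity gate | EL residual $< 10^{-3}$ | Eq-7-type forms presume EL curves |
| eigenvalue zero | $10^{-8}\max(m)/h^2$ | stiffness-scale round-off floor |
| conjugate-point refinement | $\min(h/100, h^2)$ | never caps $O(h^2)$ convergence |
| caustic `tol_first` | $10^{-6}\,\mathrm{range}(S)$ | scale-free stationarity cut |
| caustic `tol_second` | $10^{-4}\,\mathrm{median}|S_{uu}|$ | "near vanishing" is grid-relative |
| focus tag | extent $< 2$ cells | a focus is a point up to resolution |
| moment window | weight $< 10^{-16}$ of max | quadrature tail cut |
| corank threshold | $|\lambda| < 10^{-6}\times$ scale | jet-noise floor |

## Known limitations

* No continuation model past a caustic: the theory offers several
  qualitative explanations for how trajectories proceed to the native
  state and commits to none; so does this package.
* Family parameters are scalar; caustics of codimension $>2$ in the scan
  parameters are out of scope, as are chains at protein scale (hundreds of
  angles) — the Hessian scans would be the "formidable" computation the
  framework itself defers to supercomputers.
* `perturbation_stability_test()` is 1-D in state; umbilics are classified
  but not stability-tested.
* The spectral route for the second variation (expanding $\xi$ in special
  functions) is deliberately replaced by finite elements.

## A worked example

```{r example, eval = FALSE}
chain <- torsion_chain(1, 1, harmonic_spring(1, half_k = TRUE))
fam <- shoot_family(chain, function(u) list(q0 = 1, v0 = u),
                    seq(-2, 2, length.out = 21), 0, 4, 800)
surf <- family_action_surface(fam, chain)
detect_caustic(surf)          # one focus at (t, x) ~ (pi, -1)
find_conjugate_points(chain, fam$trajectories[[11]])  # t* ~ pi
```
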