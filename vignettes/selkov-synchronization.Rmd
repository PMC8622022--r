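---
title: "Synchronizing the Selkov glycolysis reaction-diffusion model"
author: "selkovsync"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synchronizing the Selkov glycolysis reaction-diffusion model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selkovsync)
```

## The model

The Selkov system is a minimal two-variable kinetic model of glycolytic
oscillations: `u1` is the autocatalytic product (ADP/F6P pool, depending on
the reduction), `u2` the substrate, and the cubic term `u1^2 u2` the
autocatalytic step.  With diffusion on a bounded domain $\Omega$ and
zero-flux boundaries the model reads

$$
\partial_t u_1 = d_1 \Delta u_1 + b u_2 - u_1 + u_1^2 u_2, \qquad
\partial_t u_2 = d_2 \Delta u_2 + a - b u_2 - u_1^2 u_2,
$$

with $\partial_\nu u_i = 0$ on $\partial\Omega$ and positive constants
$a, b, d_1, d_2$.  Two structural facts drive everything in this package:

* the reaction terms satisfy $f + g = a - u_1$, so the unique homogeneous
  steady state is $(u_1^*, u_2^*) = (a,\, a/(b+a^2))$ (for the reference
  parameters $a = 3.5$, $b = 0.25$ this is $(3.5, 0.28)$, the baseline of
  the stock initial conditions);
* solutions are nonnegative and uniformly bounded, which is what makes a
  *finite* feedback gain sufficient for synchronization.

`selkov_rhs()`, `steady_state()`, `selkov_jacobian()` and
`turing_analysis()` implement the kinetics layer.  The kinetics are written
autonomously: the time argument conventionally carried by $f$ and $g$ never
appears on the right-hand side.

## Drive-response synchronization

A second, *response*, copy of the system (states $v_1, v_2$) is coupled to
the *drive* above through additive controls $U_1, U_2$.  With the error
$e = (v_1 - u_1, v_2 - u_2)$, the open-loop error dynamics are

$$
\partial_t e_1 = d_1 \Delta e_1 + b e_2 - e_1 + (v_1^2 v_2 - u_1^2 u_2) + U_1,\\
\partial_t e_2 = d_2 \Delta e_2 - b e_2 - (v_1^2 v_2 - u_1^2 u_2) + U_2.
$$

Because the fields are bounded — say $u_1 \le K_1$, $u_2 \le K_2$,
$v_1 \le K_3$ — the cubic coupling is gain-dominated:
$|v_1^2 v_2 - u_1^2 u_2| \le K(|e_1| + |e_2|)$ with
$K = \max\{K_3^2,\, K_2 (K_1 + K_3)\}$ (`lemma2_gain()`).  The package's
control law is *defined* as the unique linear full-state feedback that turns
the open loop into linear damping $-2K$ on both error components:

$$
U_1 = -(2K - 1)\, e_1 - b\, e_2, \qquad U_2 = -(2K - b)\, e_2 .
$$

Substituted back, the closed loop is
$\partial_t e_i = d_i \Delta e_i - 2 K e_i \pm (v_1^2 v_2 - u_1^2 u_2)$, and
the Lyapunov functional $V = \tfrac12 \int_\Omega (e_1^2 + e_2^2)$ then
satisfies $\dot V \le -K \int_\Omega (|e_1| - |e_2|)^2 \le 0$ by Green's
identity, the zero-flux boundaries, and the gain-domination bound.  This is
why the closed-loop identity — `b*e2 - e1 + U1 == -2K*e1` and
`-b*e2 + U2 == -2K*e2` — is the defining *contract* of `control_law()` and
is tested to machine precision: the damping form, not any particular
coefficient rendering, is the object the stability proof uses.  The
coefficients `c11`, `c12`, `c22` are exposed as overrides so that variant
readings of the law can be reproduced; any override with damping at least
$2K$ preserves the decay argument.

Gains can be supplied directly (the reference runs use $K = 15$) or built
by the two-stage pipeline `auto_gains()`: simulate the drive and the
*uncontrolled* response over the horizon, take sup-norms of $u_1, u_2, v_1$
inflated by a safety margin (default 1.2), and apply the `lemma2_gain()`
formula.  Bounds use the supremum of the fields themselves, not absolute
values: the continuum solution is nonnegative, so any negative value is a
discretization artifact and is flagged (`positivity_violation`), never
clipped.

## Discretization and numerical choices

**Grid.**  Vertex-centered nodes on $[0, L]$ (or $[0,L]^2$), spacing
$L/(n-1)$; the reference layout is $L = 10$ with 51 nodes, spacing 0.2.
Zero-flux boundaries are realized by ghost-node mirroring (the ghost equals
the first interior value), which is second-order accurate and, combined
with the trapezoidal quadrature used for all integrals, conserves mass
*exactly* under pure diffusion (a discrete divergence theorem; tested to
1e-10 relative over the full horizon).

**Time stepping.**  Explicit forward Euler is the reference scheme.  The
diffusion-limited step is `stable_dt()` $= s\,\mathrm{dx}^2/(2\,
\mathrm{ndim}\, \max(d_1,d_2))$ with safety $s = 0.9$ by default.  The
reference horizon is $t \in [0, 100]$ with snapshots every 4 time units;
the snapshot spacing is a plotting/diagnostics interval, *not* the
integration step — an explicit step of 4 would be far beyond the stability
limit (0.02 at the reference resolution).  Integration lands exactly on
every snapshot time and on `t_end` by shortening the step before them.
Supplying an over-large `dt` deliberately does not error out at
construction: the solver warns, runs, and raises a classed `blowup_error`
naming the time reached as soon as the fields lose finiteness — NaN fields
are never returned silently.

**Controlled runs need a tighter step.**  The feedback adds linear damping
of rate $2K$ on top of the diffusive stiffness, and explicit Euler must
resolve their *sum*.  `synchronize()` therefore defaults to
`coupled_stable_dt()` $= 2s/(\rho_{\mathrm{diff}} + 4K)$, where
$\rho_{\mathrm{diff}}$ is the explicit rate of the diffusion operator
($2/\texttt{stable\_dt}$ at safety 1).  For the reference run
($K = 15$) this gives $dt = 0.01125$; the diffusion-only step 0.018 makes
that run blow up near $t \approx 0.6$.  The rule reduces to the diffusion
CFL limit as $K \to 0$.  Control is evaluated from the current error at the
beginning of each step, the same time level as the kinetics.

**Diagnostics.**  The L2 error norm uses the trapezoidal rule on the vertex
grid — consistent with the stencil order — and the Lyapunov series is by
construction $V = \tfrac12 \|e\|_{L^2}^2$ at every snapshot.  The
monotone-decrease check allows a relative slack of 1e-8 per step to absorb
floating-point noise once $V$ underflows toward zero.
`convergence_time()` returns 0 by convention when the initial error is
already zero, and `NA` when the threshold ratio is never reached.

## The pattern-formation regime

At the reference parameters the kinetics are stable (trace
$-11.54 < 0$, determinant $12.5 > 0$) but the strongly unequal diffusivities
($d_1 = 0.01$, $d_2 = 1$) destabilize a band of spatial modes:
`turing_analysis()` samples the dispersion relation on the Neumann modes
$k = m\pi/L$ and finds a maximal growth rate of about $0.096$ near
$k^2 \approx 36$.  Two consequences matter for interpreting runs:

* The sinusoidal reference initial condition feeds this band through the
  nonlinearity, so the *drive itself* develops a stationary spatial pattern
  over the horizon — synchronization here means the response locks onto a
  patterned, not a homogeneous, trajectory.
* The growth is slow: with a maximal rate of $\approx 0.1$ the amplitude
  e-folds on a $\sim 10$ time-unit scale.  A white-noise perturbation of
  the steady state first *loses* variance (most of its energy sits in
  strongly damped modes) and only later grows patterns; in the 2D
  demonstration run the spatial variance is still below its initial value
  at $t = 3$ and exceeds $10\times$ only around $t \approx 30$.  The
  package reports the $t = 3$ variance ratio as part of its acceptance
  outputs, and the corresponding early-time growth assertion in the test
  suite documents this gap deliberately rather than asserting something
  the dynamics do not do.

## The synthetic initial conditions

The package generates all of its inputs:

* `ic_drive_reference()` / `ic_response_reference()` — the smooth
  sinusoidal profiles $(3.5 + 0.1\sin x,\ 0.28 + 0.1\sin x)$ and
  $(1 + 0.5\sin 0.2x,\ 0.6 + 0.5\sin 0.2x)$; the response starts order-one
  far from the drive.  On 2D grids they extend constantly along $y$ by
  default (the separable $\sin x \sin y$ variant is available), a choice
  made once since the 2D experiments' initial conditions are otherwise
  unspecified.
* `ic_perturbed_steady()` — the steady state with multiplicative uniform
  noise of relative amplitude 0.05 by default, the conventional seeding for
  Turing-pattern studies; every draw takes an explicit seed and restores
  the caller's RNG state.

These fixtures emulate smooth laboratory-style initial profiles and
idealized noise.  They do not emulate measurement noise in time, parameter
heterogeneity across space, or stochastic reaction kinetics — passing tests
therefore certify the solver and the control law, not robustness of
synchronization to model mismatch, which full-state linear feedback does
not address.

## Problem sizes and defaults used in validation

The shipped tests and the acceptance script use the reference resolution
(51 nodes per axis, spacing 0.2) and horizon $t = 100$ in 1D; the 2D
pattern run uses $51 \times 51$ nodes to $t = 3$.  The parameter-sweep
property test exercises the auto-gain pipeline at the four corners of
$(a, b) \in [1, 4] \times [0.1, 1]$ with the reference diffusivities, at
safety factor 0.5 (the kinetic stiffness grows with $a^2$).  The negative
control (feedback zeroed) is integrated at the same step as the controlled
run; its final-to-initial error ratio is step-size sensitive (about 0.12
at the converged step, spuriously small at the marginal diffusion-limit
step), which is why both runs share solver settings.

## Known limitations

* Explicit Euler only; no IMEX or adaptive stepping.  Stiff parameter
  ranges are handled by shrinking the step, not by implicit diffusion.
* The gain construction is conservative: the pipeline's $K$ (about 63 for
  the reference run, driven by the uncontrolled response's transient
  overshoot of $v_1$) exceeds the hand-tuned $K = 15$ by a factor of four,
  and both far exceed what is empirically necessary.
* No bifurcation continuation or limit-cycle analysis of the kinetic ODE;
  the stability layer covers the homogeneous steady state and its
  dispersion relation only.
* Full-state linear feedback only — both error components are measured and
  actuated; observer-based or partial-state control is out of scope.
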