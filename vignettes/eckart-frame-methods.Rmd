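---
title: "Separating rotation from vibration: the Eckart-frame methods behind eckrot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating rotation from vibration: the Eckart-frame methods behind eckrot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eckrot)
```

## The problem

A flexible molecule in shear flow both rotates and vibrates. The standard
laboratory-frame analysis solves $J\,\omega = L$ for an *apparent* angular
velocity $\omega$, where $J$ is the instantaneous inertia tensor and $L$ the
angular momentum about the center of mass. For a rigid body $\omega$ is the
rotation rate; for a flexible body it silently absorbs every internal motion
that carries angular momentum (counter-twisting domains, swinging arms), so
it has no clean dynamical interpretation. The Eckart corotating frame fixes
this: it attaches a body frame to a reference configuration so that the
leading rotation-vibration (Coriolis) coupling vanishes, yielding a *pure*
angular velocity $\Omega$ and a five-term kinetic-energy decomposition that
isolates vibrations with and without angular momentum.

`eckrot` implements this analysis for coarse-grained bead trajectories,
together with the conformational observables used alongside it (gyration
tensor, $R_g$, RMSD, RMSF), breakable elastic-network bookkeeping, and the
open-boundary (OBMD) shear-flow boundary formulas as testable pure
functions. Everything is validated against a synthetic-trajectory generator
whose motion content is known in closed form.

## Conventions and units

Internally everything is amu / nm / ps, so kinetic energies come out in
kJ/mol without conversion factors ($1\,\mathrm{amu\,nm^2\,ps^{-2}} =
1\,\mathrm{kJ/mol}$). Generator-facing rates (prescribed angular velocities,
shear rates) are quoted in $\mathrm{ns}^{-1}$, the axis convention of the
shear-flow literature; analysis results are in $\mathrm{ps}^{-1}$ with
`per_ps_to_per_ns()` for reporting. Axes follow the shear convention:
$x_1$ flow, $x_2$ gradient, $x_3$ vorticity, with the imposed profile
$v_1 = \dot\gamma x_2$. With that profile the vorticity-direction rotation
is clockwise, i.e. $\omega_3 < 0$; comparisons against $\dot\gamma/2$ use
magnitudes.

## The model

### Laboratory frame

With $d_\alpha = r_\alpha - r_{cm}$ and relative velocities
$\dot d_\alpha$:

$$
J = \sum_\alpha m_\alpha\big(|d_\alpha|^2 I - d_\alpha d_\alpha^T\big),
\qquad
L = \sum_\alpha m_\alpha\, d_\alpha \times \dot d_\alpha,
\qquad
J\,\omega = L .
$$

The velocity splits as $\dot d_\alpha = \omega \times d_\alpha +
\tilde v_\alpha$, where the residual $\tilde v_\alpha$ carries zero total
angular momentum by construction. Hence the lab decomposition
$T = T_{trans} + \tfrac12\omega^T J \omega + \tfrac12\sum m|\tilde v|^2$
has no cross term: the Coriolis coupling is identically zero in the
laboratory frame, which the code verifies each frame as a diagnostic.

### Eckart frame

Given a reference configuration $c_\alpha$ (about its own center of mass),
the attachment rotation $R$ is the mass-weighted optimal-superposition
rotation, computed by the quaternion eigenvector method (largest eigenvalue
of the 4x4 Kearsley form). This closed-form choice provably satisfies the
Eckart condition $\sum_\alpha m_\alpha\, c_\alpha \times \rho_\alpha = 0$
with $\rho_\alpha = R^T d_\alpha - c_\alpha$; the residual norm is reported
per frame and sits at round-off ($<10^{-9}\,\mathrm{amu\,nm^2}$ on all
fixtures).

Differentiating the Eckart condition in time gives the frame's angular
velocity: with $d'_\alpha = c_\alpha + \rho_\alpha$,

$$
J' \,\Omega' = \sum_\alpha m_\alpha\, c_\alpha \times
  \big(R^T \dot d_\alpha\big),
\qquad
J' = \sum_\alpha m_\alpha\big[(c_\alpha \cdot d'_\alpha)\,I -
  d'_\alpha c_\alpha^T\big],
$$

and $\Omega = R\,\Omega'$. $J'$ is not symmetric in general; it reduces to
the reference inertia tensor when $\rho = 0$, where $\Omega = \omega$
exactly. As an independent check that this transcription is right, the test
suite compares $\Omega$ against a finite difference of the rotation history
(the skew part of $\dot R R^T$), an oracle that never touches $J'$; the two
agree to $O(\mathrm{d}t^2)$.

The vibrational velocity in the Eckart frame is
$\Delta v_\alpha = \dot d_\alpha - \Omega \times d_\alpha =
\tilde v_\alpha + u_\alpha$ with $u_\alpha = (\omega - \Omega) \times
d_\alpha$: $\tilde v$ is the angular-momentum-free part (identical to the
lab residual) and $u$ carries all the vibrational angular momentum,
$\sum m\, d \times u = L - J\Omega$.

### Kinetic-energy decomposition

$$
T = \underbrace{\tfrac12 M |v_{cm}|^2}_{T_{trans}}
  + \underbrace{\tfrac12 \Omega^T J\, \Omega}_{T^{Eck}_{rot}}
  + \underbrace{\tfrac12 \sum m |\tilde v|^2}_{T^{Eck}_{vib\text{-}non\text{-}ang}}
  + \underbrace{\tfrac12 \sum m |u|^2}_{T^{Eck}_{vib\text{-}ang}}
  + \underbrace{\Omega \cdot \sum m\, d \times \Delta v}_{T^{Eck}_{Cori}} .
$$

Both decompositions close on the direct total $\tfrac12\sum m|v|^2$ to
$10^{-10}$ relative on every fixture, and the inter-frame relations

$$
T^{lab}_{vib} = T^{Eck}_{vib\text{-}non\text{-}ang},
\qquad
T^{lab}_{rot} = T^{Eck}_{rot} + T^{Eck}_{vib\text{-}ang} + T^{Eck}_{Cori}
$$

hold frame by frame (`frame_relations()`): the vibration carrying angular
momentum and the (possibly negative) Coriolis coupling live inside the lab
rotational term. The Coriolis term vanishes identically on rigid and on
breathing fixtures and grows in magnitude - going negative - as vibrational
angular momentum is injected.

A note on the rotational term: $T^{Eck}_{rot}$ uses the *instantaneous*
inertia tensor $J$, not $J'$. With the non-symmetric $J'$ the five terms
would not recompose the total kinetic energy; with $J$ the closure is exact
by algebra, and the two coincide for vanishing displacements.

## What "the Eckart frame minimizes the Coriolis coupling" means

This folk statement needs care, and the package makes the distinction
explicit:

* The coupling **energy** $T_{Cori} = \Omega\cdot(L - J\Omega)$ is
  *stationary* at the Eckart attachment but not minimal: a small static
  reorientation changes the coupling vector at first order in the
  perturbation times first order in the vibrational velocities, while the
  Eckart value is already second order, so roughly half of random small
  perturbations lower its magnitude. We measured exactly that on rigid+twist
  fixtures before settling the design.
* The **leading coupling term** $\big|\sum_\alpha m_\alpha c_\alpha \times
  \dot\rho_\alpha\big|$ - the term Eckart's conditions were chosen to
  annihilate, with the frame angular velocity unchanged by a static
  reorientation - is exactly zero at the Eckart rotation and positive for
  any other attachment. This is the precise sense in which "any other frame
  gives a larger Coriolis coupling".

`coriolis_coupling(what = "condition")` exposes the second functional and
the perturbation test (100 random rotations of up to 5 degrees per fixture
frame) verifies the minimization without exceptions;
`coriolis_coupling(what = "energy")` keeps the signed decomposition term.

## Why angular velocities are compared after time averaging

For any motion, $J(\omega - \Omega) = R\sum m\,\rho\times\dot\rho$: the
apparent and Eckart angular velocities differ only at *second order* in the
vibration amplitude, and both carry the identical first-order oscillating
leakage from vibrational angular momentum (for a twist,
$\dot\theta\,\Delta I/I$). Per-frame absolute errors against a prescribed
rotation are therefore statistically indistinguishable. What distinguishes
the frames is the *rectified* second-order bias: on rigid+twist composites
the time-averaged apparent velocity $\langle\omega_3\rangle$ is biased away
from the prescribed rate by an amount growing like the squared twist
amplitude, while $\langle\Omega_3\rangle$ is 20-150 times closer to the
truth on the same fixtures. This mirrors how such analyses are reported in
practice - production-run averaged angular velocities versus shear rate -
and it is the comparison the acceptance test makes.

## The synthetic world

The generator produces trajectories whose decomposition is known exactly;
velocities are always analytic, never finite-differenced (a central
difference fallback exists for velocity-free inputs, exact for linear
motion and $O(\mathrm{d}t^2)$ otherwise):

* `make_rigid_rotor()` - pure rotation at a prescribed rate about the COM;
  lab and Eckart frames must coincide to $10^{-10}$ relative.
* `make_breathing()` - radial scaling $1 + a\sin(2\pi f t)$; purely radial
  velocities, so total angular momentum is the zero vector every frame and
  everything lands in $T_{vib\text{-}non\text{-}ang}$.
* `make_twist()` - halves split by the sign of the coordinate along the
  axis counter-oscillate azimuthally: a vibration carrying angular momentum
  whenever the halves' axis inertias differ; beads on the dividing plane
  stay put, making the partition unambiguous.
* `make_shear_cloud()` - beads on a cubic lattice inside a sphere (a set
  exactly closed under coordinate permutations and sign flips, so
  $\sum m x_1^2 = \sum m x_2^2$ holds *exactly*) with $v_1 = \dot\gamma
  x_2$. The Einstein sphere limit $|\omega_3| = \dot\gamma/2$ then follows
  analytically rather than statistically, to $10^{-12}$.
* `compose_motions()` - lab-frame superposition of displacement and
  velocity fields plus a uniform COM drift, with the ground truth recorded
  in a JSON sidecar. (A body-frame composition - vibrating in the
  corotating frame - was also evaluated and gives the same qualitative
  behavior; the simpler superposition contract is kept.)
* `make_toy_protein()` - a compact self-avoiding chain (consecutive
  spacing = bond length, minimum separation $0.9\times$ that) used as the
  elastic-network and observables fixture.

Default fixture scales follow the source application: 0.35 nm bead
spacing and 72 amu beads (generic 4-heavy-atom coarse-grained beads), a
0.02 ps integration-step culture with analysis frames every 0.5-1 ps,
prescribed rotations of a few $\mathrm{ns}^{-1}$ and shear rates of
5-50 $\mathrm{ns}^{-1}$, twist amplitudes 0.1-0.3 rad at 0.02
$\mathrm{ps}^{-1}$. What the generator does *not* emulate: thermal noise,
solvent collisions, force-field dynamics, tumbling statistics. A green test
therefore establishes the correctness of the kinematic decomposition
machinery, not the physics of any particular protein.

## Elastic network

`build_en()` places one harmonic bond per bead pair whose reference
separation lies in the 0.5-0.9 nm window (force constant
550 kJ mol$^{-1}$ nm$^{-2}$), with $r_0$ the observed distance;
`assign_break_cutoffs()` sets $R_c = 1.35\,r_0$, the multiplier calibrated
so an equilibrium-like trajectory conserves the network. Breaking is
irreversible and evaluated at sampled frames only - this package analyzes
trajectories, it does not integrate dynamics, so a bond that exceeds its
cutoff *between* frames is seen at the next sample. A broken pair leaves
the harmonic energy and is recorded as an event (the hand-off of the pair
to nonbonded bookkeeping is out of scope, as no force field is evaluated
here). The breaking test is instantaneous-distance based; no smoothing is
applied.

## Boundary formulas

The OBMD machinery is exposed as pure functions in caller-chosen consistent
units: the momentum-flux tensor of the linear shear profile
($J^P_{11} = \rho\dot\gamma^2x_2^2 + p$, $J^P_{12} = J^P_{21} =
-\eta\dot\gamma$, $J^P_{22} = J^P_{33} = p$), the buffer momentum balance
$F^{ext} = A\,(J^P_{22}\,n + J^P_{12}\,t) - \sum \Delta(mv)/\delta t$, the
per-particle force distribution with pluggable $g_\parallel, g_\perp$
weights (normalized so the particle forces sum to $F^{ext}$ exactly - the
functional forms of the weights are not pinned by the source, so uniform
weighting is the default behind a pluggable spec), the standard DPD weight
pair $\omega^R = 1 - r/r_c$, $\omega^D = (\omega^R)^2$ (the
fluctuation-dissipation identity $\omega^D = (\omega^R)^2$ is asserted on
sweeps), and the buffer feedback $\Delta N_B = (\delta t/\tau_B)
(\langle N_B\rangle - N_B)$, a contraction for $\delta t < \tau_B$. The
bulk-viscosity term $\pi = -\zeta\,\nabla\cdot v$ is carried in the
parameter set but enters no implemented component: the linear shear profile
is divergence-free.

## Numerical choices, degenerate inputs, limitations

* Orthogonality of every attachment rotation is enforced to $10^{-10}$ and
  the quaternion construction yields a proper rotation by construction
  (reflection-dominant optima cannot occur; near-degenerate top eigenvalues
  of the Kearsley form - e.g. planar-symmetric bead sets - set a
  `degenerate` flag).
* Collinear bead sets make $J$ (and $J'$) singular: solves fall back to an
  SVD pseudo-inverse with an explicit `degenerate` flag rather than
  failing silently.
* The reference configuration defaults to the trajectory's own structure;
  a minimized structure can be supplied, and `analyze_rotation()` can
  re-reference every $N$ frames - provided because re-referencing was
  checked in the source application and found immaterial, a result the test
  suite reproduces on rigid fixtures.
* RMSF uses the time-mean position after per-frame superposition onto the
  reference (reference choice and superposition protocol are toggles, since
  conventions differ between codes).
* Observables are mass-weighted by default, with a flag for the unweighted
  variant; with equal bead masses the two coincide.
* Block-averaged standard errors use non-overlapping blocks (default 50
  frames); with block length 1 this reduces to $\mathrm{sd}/\sqrt{N}$.
* Energy fractions are reported both relative to the total and relative to
  the internal (total minus translational) energy, since either
  normalization is defensible for "relative contributions".
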