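---
title: "Recovering hidden material abnormalities from surface deformation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering hidden material abnormalities from surface deformation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A soft body (a silicone beam, an inflatable balloon, an aortic valve
leaflet) hides an internal abnormality: a region that is stiffer, or
thicker, than its surroundings. Cutting the body open is not an option -
the clinical motivation is calcific aortic valve disease, where stiff,
thickened calcium patches on the leaflets must be assessed in vivo. What
*can* be observed is how the body's surface deforms under a known load:
keypoint trajectories from ultrasound, CT, or plain video tracking.

`softinverse` recovers the hidden physical information from those
trajectories. A finite-element *virtual twin* of the body is built whose
free parameters are the unknowns: per-region Young's moduli `E`,
membrane thicknesses `T`, and the position and shape of the abnormal
region. The twin is loaded exactly like the physical body, its simulated
keypoint trajectories `D_hat(x)` are compared with the observation `D`
through the squared trajectory mismatch

    L(x) = || D - D_hat(x) ||^2 ,

and a gradient-free batch Bayesian optimizer seeks

    (M*, P*, S*) = argmin L(x)

over materials `M`, abnormality position `P` and shape `S`
simultaneously. When the simulated and observed deformations match, the
twin's parameters are the estimate of the hidden physical state.

## The forward model

### Constitutive laws

The soft materials are incompressible Neo-Hookean solids with strain
energy `W = mu/2 (lambda1^2 + lambda2^2 + lambda3^2 - 3)`, `mu = E / (2(1
+ nu))`, `nu = 0.5`. The Cauchy stress of the incompressible model is
`sigma = mu F F^T - p I` with the pressure `p` enforcing `det F = 1`.
A Saint Venant-Kirchhoff variant (`S = lambda tr(E) I + 2 mu E`) is used
to generate cross-model observations, testing that recovery does not
depend on both sides of the inversion sharing a constitutive law.

A displacement-based finite-element solver cannot impose `det F = 1`
exactly, so the solver uses the standard nearly-incompressible split: an
isochoric Neo-Hookean term plus a volumetric penalty `kappa/2 (J - 1)^2`
with `kappa` derived from an effective Poisson ratio of 0.499. The
constitutive module exposes both forms; the exact-incompressible
principal-stretch form is what the closed-form test oracles use
(uniaxial `sigma11 = mu (lambda^2 - 1/lambda)`, spherical membrane
`P = 2 mu (t/R)(lambda^-1 - lambda^-7)`).

### Discretization and solver

Solid bodies are meshed with 8-node hexahedra. The isochoric term is
integrated at 2x2x2 Gauss points and the volumetric penalty at the
element center only (selective reduced integration), which avoids
volumetric locking as `nu -> 0.5`; the single-element uniaxial test
reproduces the incompressible closed form to 0.1%. Thin structures (the
valve leaflets) use 3-node constant-strain membrane triangles with an
exactly plane-stress-incompressible Neo-Hookean law; they carry no
bending stiffness, which has one identifiability consequence discussed
below. Pressure is a follower load (it acts along the deformed surface
normal), which matters at the strains the balloon reaches.

Element tangent matrices are central-difference derivatives of the
analytic element residuals. This keeps every material variant exactly
consistent with its residual at the cost of a constant factor in
assembly time - negligible at the mesh sizes the benchmarks use, and the
central difference is required: with a 1000x stiffness contrast between
regions, one-sided differences leave Newton with a slow linear tail.

Equilibria are found by Newton's method with load incrementation,
automatic step halving (down to 1/64 of an increment), an increment cap
of twice the smallest element edge, and a line search. Two line-search
policies are used: transient steps backtrack monotonically on the
residual norm, while static steps tolerate transient residual growth up
to a factor of 100 (Newton on follower-pressure problems routinely
overshoots before collapsing quadratically) and abort only on outright
divergence. Convergence demands a 1e-10 relative residual reduction *or*
displacement stagnation (a full Newton step moving the iterate by less
than 1e-11 relative) - the latter because the absolute residual floor is
set by roundoff of the stiffest elements, and a pure relative criterion
dead-locks small load increments on high-contrast meshes.

### Why the beam runs in transient mode

The beam benchmark is loaded purely kinematically: the left face is
fixed and the right face is displaced upward by 30 mm. A quasi-static
solve with displacement-only boundary conditions has a fundamental blind
spot: scaling *all* moduli by a common factor leaves the equilibrium
displacement field unchanged, so only modulus *ratios* are identifiable
and `E_b` itself is not. The benchmark tables, however, state a density
(1 kg/mm^3) and the reference results were produced with a dynamic
solver - inertia is what makes the absolute stiffness scale observable.

The solver therefore has a transient mode: implicit Newmark integration
(gamma = 0.6, beta = (gamma + 1/2)^2/4, i.e. with numerical dissipation
so unresolved high-frequency modes decay rather than ring), lumped mass,
and mass-proportional damping. The beam cases use the stated density
literally with a ramp duration of 500 s and damping of 0.1 /s. These two
numbers are not printed anywhere and were calibrated once, by forward
physics only: they make the inertial/viscous signature of the response a
clear fraction of the trajectory norm (the loss curvature along the
modulus-scaling ray is comparable to the curvature across it, ~25-100
per decade^2 in log10 coordinates) while the deformation stays
bending-dominated and the solver converges over the whole 8-decade
search box. The "time" axis of a trajectory is the load-step axis; the
desk preset records 5 steps, the reference preset 10.

The valve also runs in transient mode, with strong viscous damping
(1e6 /s) playing the role of a pseudo-transient regularization: membrane
shells without bending stiffness have locally singular static tangents
(wrinkling), and the damped transient is a deterministic, smooth-in-
parameters forward map that reaches a near-static state over the ramp.
It is not a hemodynamic simulation.

## Abnormality parameterizations

The beam's abnormality is a brick spanning the cross-section, described
by axial center `C` and half-width `W`. The balloon and valve use the
revolved generator `R(theta) = R0 (1 + C1 cos 4 theta + C2 cos 8 theta)`
rotated about the z-axis of a frame translated by `(Px, Py, Pz)`;
`theta` is taken as the polar angle from the local +z axis, so a point
is inside when its distance from the center is at most `R(theta)`.
Elements are labelled abnormal when their *centroid* falls inside
(boundary inclusive). Centroid labelling makes counts exact and
deterministic, at the cost of quantizing recoverable geometry to the
element size - on the desk beam mesh the zero-loss plateau for `C` is
about +/- 2.5 mm wide, which is why geometric parameters are reported
but only the moduli carry tight accuracy claims.

## The optimizer

The loss is expensive (a nonlinear FE solve per evaluation), gradient-
free, and multi-modal at the scale of the search box; moduli are sought
over 1e2..1e10 Pa. The optimizer is a batch-sequential surrogate loop:

1. A seeded Latin hypercube design (`n0 = 2d + 2` by default) in encoded
   coordinates; moduli and thicknesses are log10-encoded, geometry is
   linear.
2. A bootstrap random forest (100 trees, per-tree predictions supplying
   the empirical variance `s^2(x)`) is fit to the evaluations.
3. `q` candidates per iteration (default 8): each batch member draws its
   own temperature `t ~ Lognormal(0, 1)` and maximizes the moment-
   generating-function infill

       M(x, t) = Phi((Lmin - Lhat')/s) * exp((Lmin - Lhat - 1) t + s^2 t^2 / 2),
       Lhat' = Lhat - s^2 t,

   which reduces to the probability of improvement at `t = 0` and trades
   exploration (large `t`) against exploitation (small `t`). The inner
   maximizer is a self-adaptive (4+28) evolution strategy over the
   encoded box, run for 50 generations, seeded partly at the best
   evaluated configurations. Acquisition evaluation is done in log space
   and clamped, so extreme temperatures cannot overflow.
4. The proposals are evaluated (optionally in parallel; results are
   identical to sequential evaluation for a deterministic objective),
   appended, and the forest refit. Failed forward solves enter the
   history as `+Inf` and are replaced, for fitting only, by ten times
   the largest finite loss.

Two design details matter far more than any tuning knob:

* **Variance stabilization.** The forest is trained on
  `log10(loss + offset)` (offset = the convergence tolerance). Raw
  losses span ten or more decades, and a variance-reduction tree spends
  its entire resolution on the high-loss plateaus - the fitted surrogate
  is then *blind* near the optimum and the loop stalls at percent-level
  accuracy. On the log scale the basin bottom carries as much structure
  as the plateaus, and the same loop reaches sub-0.1% moduli accuracy.
  The transform is monotone, so the argmin - and the reported losses -
  are unchanged.
* **Duplicate re-anchoring.** A piecewise-constant surrogate makes the
  acquisition flat inside its best leaf, so the inner maximizer often
  returns a point the history has already resolved (within the local
  sample spacing). Such proposals are re-mutated once from an anchor -
  usually the incumbent, sometimes another of the better evaluated
  points, so local search is not captive to a single possibly-spurious
  mode - at random log-uniform scales tied to the local spacing. Half of
  these moves perturb a single coordinate only: in anisotropic basins
  most progress comes from changing one parameter at the right scale
  while holding the already-resolved ones. Small scales refine the
  optimum geometrically; large ones probe weakly-determined directions
  that the forest cannot extrapolate over.
* **Interleaved exploration.** A quarter of every batch is drawn
  uniformly from the search box. Improvement-based criteria can never
  justify crossing a worse-than-incumbent ridge, yet the benchmarks are
  genuinely multi-modal - the beam, for instance, admits a label-swapped
  near-solution (a soft "abnormality" covering the complement of the true
  inclusion with both moduli rescaled) whose basin undercuts the ridge
  around the true one. Unconditional sampling is the standard guarantee
  against such deceptive modes in forest-based optimization.

The loop stops at the evaluation budget or as soon as the best loss
drops below `1e-12 (1 + ||D||^2)` - an essentially exact trajectory
match, reachable only in inverse-crime mode.

The temperature default follows the algorithm's sampled form; a fixed
temperature mode (`t = 2`) is also available, since both appear in the
method's own description and neither dominates the other in our tests.

### A gauge freedom of the brick parameterization

When the brick abnormality touches one end of the beam, labelling its
*complement* as abnormal and exchanging the two moduli produces the
identical element-wise material field - the deformation data cannot
distinguish the two parameterizations, and the inverse problem has two
exactly equivalent global minima. The benchmark convention (and the
physical reading) is that the abnormality is the *stiffer* region, so
recovered estimates that converged to the swapped gauge are mapped back
to that convention before errors are reported. This is a resolution of a
parameterization symmetry, exactly like fixing the sign of a principal
axis; it changes no loss value and no search behaviour.

## Benchmarks and the synthetic-data generator

`registered_cases()` holds thirteen cases; `generate_observation()`
produces the observation by running the forward solver at the printed
ground truth ("inverse crime" mode - deliberately, so that recovery
error measures the optimizer, not model mismatch), optionally adding
i.i.d. Gaussian noise with standard deviation `noise_sigma * max|D|`.

* **Beam** (cases 1-4 + cross-model): 50 x 25 x 3 mm, E_b = 1e3 Pa,
  brick abnormality (E_a = 1e6 Pa, C = 40 mm, W = 10 mm), left face
  fixed, right face ramped +30 mm, four keypoints on the long edge,
  bounds 1e2-1e10 Pa, C in [0, 50], W in [0, 25]. The cross-model case
  generates the observation with the Saint Venant-Kirchhoff solver and
  inverts with Neo-Hookean.
* **Balloon** (cases 1-4): radius 100 mm, thickness 3 mm, internal
  pressure 8 Pa (about two thirds of the Neo-Hookean limit-point
  pressure of the homogeneous shell), revolved-generator abnormality
  with R0 = 41.2 mm, C1 = 0.47, C2 = -0.35, P = (-4.5, 62.1, 65.7) mm;
  all mesh vertices are tracked. The stated position search range
  ([0, 200] mm) does not contain the stated truth (P_x = -4.5), so the
  package uses [-200, 200] mm.
* **Valve** (cases 1-4): simplified parametric tri-leaflet membrane
  surface on a 12.5 mm annulus, healthy AS_b = 1e6 Pa x 0.3 mm,
  calcified AS_a = 1e9 Pa x 0.9 mm, 10 kPa trans-valvular pressure,
  lower edges fixed. The fixture's patch truth (R0 = 4, C1 = 0.2,
  C2 = -0.1, P = (7, 0, -1.5) mm) is a package choice (a mid-belly
  patch); annulus radius and pressure are documented assumptions. The
  tracking rule takes the largest-deformation upper-half node of *each*
  leaflet: the global top-3 all land on the healthy leaflets and carry
  no information about the patch. Because membranes have no bending
  stiffness, `E` and `T` enter the response only through `E * T`: the
  arterial stiffness `AS` is identifiable and reported, the E/T split
  is not.

Each case carries a coarse "desk" mesh preset (beam 10 x 2 x 2, balloon
96 shell elements, valve ~250 triangles) and a finer "reference" preset
(beam 20 x 6 x 4, etc.); results are stamped with the preset used. Desk
problem sizes were chosen so a full beam recovery (about 300 forward
solves) completes in minutes.

What inverse-crime observations deliberately do *not* emulate: tracking
noise (available separately via `noise_sigma`), model error (the
cross-model case probes one slice of it), miscalibrated boundary
conditions, and real imaging geometry. Passing benchmarks therefore
demonstrates the identification machinery, not clinical readiness.

## Shape scoring

Recovered abnormality shapes are compared to the generating shapes as
binary masks: the balloon through an equirectangular spherical-map
projection of the northern hemisphere (each pixel takes the label of the
nearest element centroid in great-circle distance), the valve through a
PCA projection of abnormal-element centroids onto their two leading
principal axes - fitted on the union of truth and estimate so both masks
share axes, with signs fixed by the first point's score. Masks are
scored with SSIM (Gaussian 7x7 window, sigma 1.5, K1 = 0.01, K2 = 0.03,
dynamic range 1, mean over valid windows; 1 for identical masks).
Absolute SSIM values depend on the raster resolution (default 128x128)
and window, which the mask records in its projection descriptor.

## Numerical choices, degenerate inputs, limitations

* Candidate abnormalities selecting zero elements are legal and run as
  homogeneous bodies; `R0 <= 0` and `W <= 0` are treated the same way.
* Candidates whose forward solve fails report `+Inf` loss; the run
  continues.
* Transient steps never subdivide their time step (that would change
  the integrator, making the loss discontinuous in the parameters);
  they get a 300-iteration Newton allowance instead.
* Observation files with a different step count than the solver's are
  linearly interpolated in load fraction on reading.
* The desk-scale recovery accuracy is optimizer-limited, not
  solver-limited: with a few hundred evaluations the beam moduli come
  back at the 0.1% level; the balloon/valve shape searches (7-10
  dimensions) need far larger budgets to reach their reference scores
  and are run as long-budget jobs rather than in the default test
  suite.
* Recoverable geometry is quantized by the element size (centroid
  labelling); refine the mesh preset to tighten it.
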