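# softinverse

Non-destructive recovery of hidden material parameters and internal
abnormalities in soft bodies, from surface deformation alone.

## The problem

A soft object — a silicone beam, an inflatable membrane, an aortic valve
leaflet — contains a hidden region that is stiffer (or thicker) than its
surroundings: an inclusion, a damaged patch, a calcification. Only the
object's surface motion under a known load can be observed, as keypoint
trajectories from video tracking, ultrasound or CT. `softinverse`
identifies the hidden physical state by *deformation matching*: it builds
a finite-element **virtual twin** of the object, simulates the same load
program, and tunes the twin's free parameters until the simulated
keypoint trajectories match the observed ones.

With `D` the observed trajectories and `D̂(x)` the simulated ones at
parameters `x`, the method minimizes the trajectory mismatch

```
L(x) = ‖D − D̂(x)‖²,     (M*, P*, S*) = argmin L(x)
```

jointly over material parameters `M` (per-region Young's moduli `E`,
membrane thicknesses `T`), abnormality position `P` and shape `S`. The
loss is expensive (a nonlinear finite-element solve per evaluation) and
gradient-free, so the minimization uses **batch Bayesian optimization**:
a random-forest surrogate with tree-variance uncertainty `s²(x)`, and the
moment-generating-function (MGF) infill criterion

```
M(x, t) = Φ((Lmin − L̂′)/s) · exp((Lmin − L̂ − 1)·t + s²t²/2),   L̂′ = L̂ − s²t,
```

whose temperature `t ~ Lognormal(0, 1)` (one draw per batch member)
trades exploration against exploitation; at `t = 0` it reduces to the
probability of improvement. A self-adaptive (4+28) evolution strategy
maximizes each criterion, and the `q` proposals per iteration are
evaluated and fed back into the forest.

The forward solver supports nearly-incompressible Neo-Hookean and Saint
Venant-Kirchhoff materials, 8-node hexahedra with selective-reduced
volumetric integration, membrane triangles, follower pressure loads, and
quasi-static or transient (Newmark) stepping.

## Worked example: finding a stiff inclusion in a bending beam

The `beam_case4` benchmark hides a brick-shaped inclusion (Young's
modulus 1 MPa, axial span 30–50 mm) in a 50 × 25 × 3 mm silicone-soft
beam (1 kPa). The left face is clamped and the right face ramped 30 mm
upward; four keypoints along the long edge are tracked. All four
parameters — both moduli `E_b`, `E_a` and the inclusion's center `C` and
half-width `W` — are unknown, searched over 10²–10¹⁰ Pa and the full
beam geometry.

```r
library(softinverse)

case <- get_case("beam_case4", mesh_preset = "desk")
obs  <- generate_observation(case)   # "inverse crime": observation from the same solver

res <- run_inverse(case, obs,
                   optimizer = bo_config(q = 8, n0 = 10,
                                         budget = 10 + 8 * 40, seed = 1))
res
```

```
<recovery_result> beam_case4: loss 2.446e-05 after 330 evaluations (40 iterations)
  E_b  = 998.882 (rel. error 0.112%)
  E_a  = 999559 (rel. error 0.0441%)
  C    = 48.8259 (rel. error 22.1%)
  W    = 16.3473 (rel. error 63.5%)
```

Both moduli come back within ~0.1% of the generating values (1 kPa and
1 MPa). The geometric estimates look far from the generating `C = 40`,
`W = 10` — but they are not: elements are labelled abnormal by centroid
membership, so any brick selecting the same element set is *exactly*
equivalent, and `[C - W, C + W] = [32.5, 65.2]` clipped to the beam
selects precisely the true 30–50 mm column set on the coarse mesh. The
final loss of 2.4e-5 mm² (against a trajectory norm of ~4.6e3 mm²) says
the simulated and observed motions are indistinguishable; geometry is
recoverable only up to the mesh quantization, which is why the accuracy
claims attach to the moduli.

The same interface drives the other benchmarks: an inflating balloon
with a star-shaped stiff patch (`balloon_case1` … `balloon_case4`,
recovered shapes scored by SSIM on spherical-map projections) and a
simplified tri-leaflet aortic valve with a calcified patch
(`valve_case1` … `valve_case4`, reported as arterial stiffness
`AS = E·T`). `registered_cases()` lists all thirteen.

There is also a thin command line:

```sh
Rscript inst/cli/softinverse list-cases
Rscript inst/cli/softinverse forward beam_case4 -o tracks.csv
Rscript inst/cli/softinverse invert beam_case4 --observed tracks.csv -o result.json
Rscript inst/cli/softinverse report result.json
```

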