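# sphtrack

Sub-Riemannian geodesic tracking of blood vessels in *spherical* images of
the retina.

Fundus photography flattens a curved retinal surface onto an image plane.
The central projection of the schematic (reduced) eye distorts lengths by up
to 7% and areas by over 20% across the field of view, which biases geometric
biomarkers such as vessel curvature. `sphtrack` avoids this by doing the
tracking in *object coordinates on the sphere*: a curve on the retinal
sphere with positions and directions prescribed at both ends is found as the
minimizer of

```
L(n) = ∫ C(n(s)) √(ξ² + k_g²(s)) ds
```

where `s` is spherical arclength, `k_g` the geodesic curvature of the curve
on the sphere, `ξ > 0` a stiffness parameter, and `C ≥ δ > 0` an external
cost derived from the image (low on vessels). The problem is lifted to a
sub-Riemannian (SR) optimal-control problem on the rotation group SO(3): a
point is a triple `(x, y, θ)` (latitude, longitude, orientation), motion is
restricted to the span of a "spatial" generator `X1` and an "angular"
generator `X2`, and the SR length is `∫ C √(ξ²u₁² + u₂²) dt`. The package
provides:

* **Schematic-eye optics** (`camera_model`, `retina_project`,
  `retina_unproject`, `camera_jacobian`, `global_distortion`): the closed-form
  projection between spherical object coordinates and flat camera
  coordinates, its exact inverse, and distortion measures.
* **Exact SR geodesics** (`exponential_map`, `geodesic_closed_form_t`,
  `cuspless_geodesic_s`, `vertical_solution_s`, `cusp_arclength_smax`,
  `wavefront`): the Hamiltonian flow of the uniform-cost problem, closed
  forms in both SR and spherical arclength (pendulum phase in Jacobi
  elliptic functions; rotation rebuilt from the conserved spatial momentum
  vector), and the first-cusp analysis that delimits where the spherical
  projection of a geodesic is a valid image curve.
* **Anisotropic eikonal solver** (`solve_eikonal`, `metric_matrix`,
  `level_set`): the SR distance map `W` as the viscosity solution of
  `√((X₁W)²/ξ² + (X₂W)²) = C` on a `(x, y, θ)` chart grid, via a Riemannian
  approximation with anisotropy `ε` and adaptive (Selling) upwind stencils;
  fast-marching and Gauss–Seidel drivers cross-validate each other.
* **Vesselness cost** (`vesselness`, `external_cost`): multiscale Hessian
  vesselness of the flat image, lifted to the chart through the eye model as
  `C = (1 + VF/(λ‖VF‖²∞))⁻¹`.
* **Tracking** (`backtrack`, `track_vessel`, `curvature_from_W`,
  `planar_curvature`): geodesic backtracking through the distance map, with
  geodesic curvature read directly from `W` as `k_g = ξ² X₂(W)/X₁(W)` — the
  curvature biomarker measured on the sphere, where it is free of projection
  distortion.
* **Synthetic phantoms** (`s_tube_spec`, `make_phantom`,
  `make_geodesic_fixture`): seeded spherical vessel phantoms with ground
  truth, so the whole pipeline is testable without data downloads.

Result objects are tibbles (or carry them) with `tidy()`, `glance()` and
`autoplot()` methods.

## Worked example

```r
library(sphtrack)

cam <- camera_model()                      # a = 13/21, c = 4/5, eta = 1
max_object_angle(cam, pi / 8)              # 0.6319 rad: the field of view
camera_jacobian(cam, 0, 0)                 # 0.7682: area shrink at center
camera_jacobian(cam, 0.63, 0.63)           # 1.1103: area stretch at the rim
global_distortion(cam, 0.63)               # 0.0701: 7% length distortion

pr <- model_params(xi = 1.5)
cusp_arclength_smax(0.4, 0.3, pr)          # 0.960042: first cusp arclength
path <- cuspless_geodesic_s(0.4, 0.3, pr, seq(0, 0.8, length.out = 5))
tidy(path)
#>   param     x       y theta    h1    h2    h3    u1    u2   k_g
#> 1   0   0      0      0     1.37  0.4   0.3   0.611 0.4   0.655
#> 2   0.2 0.199 -0.0142 0.146 1.32  0.471 0.408 0.588 0.471 0.800
#> 3   0.4 0.393 -0.0639 0.342 1.24  0.565 0.537 0.550 0.565 1.03
#> 4   0.6 0.570 -0.168  0.632 1.09  0.687 0.693 0.484 0.687 1.42
#> 5   0.8 0.702 -0.354  1.10  0.804 0.844 0.884 0.357 0.844 2.36
```

The table is the geodesic in spherical arclength: chart coordinates,
left-invariant momenta (`h1` stays positive — no cusp yet), controls and the
geodesic curvature `k_g = ξ² h2/h1`, which grows as the path approaches its
cusp at `s ≈ 0.96`. `glance(path)` reports conservation diagnostics
(`max_dev_2H`, `max_dev_M2` at machine precision).

End-to-end tracking on a synthetic phantom:

```r
ph  <- make_phantom(s_tube_spec(seed_rng = 42))   # dark S-shaped tube
cfg <- track_config(xi = 3, lam = 50, grid = c(51, 121, 121))
tr  <- track_vessel(ph$image, seed_pt = group_point(-0.114, -0.491, -2.182),
                    end_pt = group_point(0.114, 0.491, -2.182), cfg)
glance(tr)          # SR length, sample count, cusp-suspect count
tidy(tr)            # per-sample chart coordinates, k_g, planar curvature
```

A thin command-line wrapper lives in `exec/sphtrack`
(`project`, `unproject`, `geodesic`, `phantom`, `cost`, `eikonal`, `track`).

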