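---
title: "Cylindrical-shell geometry of semilunar valve cusps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cylindrical-shell geometry of semilunar valve cusps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(valvegeom)
```

## The model

`valvegeom` describes one cusp of a fully open semilunar valve as a portion
of a cylindrical shell. The modelling assumptions are:

* the valve is fully open and static — no closure, coaptation or cardiac
  cycle motion;
* the `n` cusps (3 by default) are identical and arranged with perfect
  rotational symmetry about the valve axis, so the full valve is one cusp
  rotated by multiples of `2*pi/n`;
* the cusp surface lies exactly on a circular cylinder whose axis is the
  flow axis; thickness is ignored (the surface is a zero-thickness shell);
* the free (upper) edge, viewed in the flattened development of the
  cylinder, is a half-period sine arch pinned to zero at both commissures.

Under these assumptions two measured lengths determine everything: the cusp
width `W` (arc distance between attachment pedicles along the annulus, mm)
and the maximum height `h` (free edge to attachment midpoint, mm). The
cylinder radius follows from the arc-length relation `W = r * 2*pi/n`, so
`r = n*W/(2*pi)`; the surface is

$$(\theta, z_{frac}) \mapsto
  (r\cos\theta,\; r\sin\theta,\; z_{frac}\, h \sin(k\theta)),
  \qquad \theta \in [0, 2\pi/n],\; z_{frac} \in [0,1],$$

with wavenumber `k = pi*r/W`, which is exactly `n/2` for any valid `W`.
Constructing `k` from first principles rather than hard-coding a numeric
factor keeps the model valid for arbitrary dimensions and cusp counts; for
the default instance the value agrees with the commonly quoted rounded
factor to better than 5 parts in 10^5.

Because a cylinder is developable, flattening (`x = r*theta`) preserves
lengths and areas. The cusp area is therefore the exact sine integral
`2*h*W/pi`, the annulus circumference is `2*pi*r = n*W`, and the diameter
`2*r`. The orifice (or "valve flap") area is derived from the total cusp
area by a flap-to-valve area ratio taken from cadaveric literature; it is a
plain argument (default 1.55) rather than a buried constant, so other
ratios can be studied. Note that "orifice area" and "flap area" name the
same derived quantity here; the package uses the single field
`orifice_area`.

```{r}
cusp <- pv_cusp(width = 20.211, max_height = 14.20, n_cusps = 3)
valve_measurements(cusp)
```

The default width 20.211 mm and height 14.20 mm are the conventional
approximate dimensions of an adult human pulmonary valve cusp; the bundled
per-cusp morphometric table (`pulmonary_morphometry()`) gives the published
population means and SDs (widths ≈ 21.4–21.6 mm, heights ≈ 11.8–12.1 mm).
The defaults are a single round-number instance near that population, not
its mean; the package takes dimensions as inputs and does not attempt to
reconcile the two.

## Parameters that matter

| parameter | units | default | role |
|---|---|---|---|
| `width` | mm | 20.211 | cusp width; sets `r` and the sine period |
| `max_height` | mm | 14.20 | free-edge peak height; sets the sine amplitude |
| `n_cusps` | — | 3 | valve symmetry; sets angular extent `2*pi/n` and `k = n/2` |
| `flap_to_valve_ratio` | — | 1.55 | divides total cusp area into orifice area |
| `n_theta`, `n_z` | — | 128, 64 | mesh grid resolution per cusp |

## Numerical choices

* **Coordinate frame.** The valve axis is global +z (flow direction), the
  annulus circle lies in the z = 0 plane, and the first cusp spans
  `theta` in `[0, 2*pi/n]`. Nothing anatomical fixes a global frame; this
  choice makes rotation assembly and flattening trivial.
* **Interior parameterization.** The surface interior uses
  `zfrac` in `[0, 1]` scaling the local free-edge height, so the parameter
  domain is a fixed rectangle. This is equivalent to bounding `z` by the
  sine directly, and it simplifies structured meshing.
* **Tolerances.** Closed-form identities (flatten/unflatten round trips,
  arc-length consistency, report self-consistency) are held to 1e-12
  relative; fitted or iterative quantities to 1e-6 or better; points are
  accepted as lying on the cylinder at 1e-9 relative residual.
* **Free-edge fitting.** `fit_sine_boundary()` fits `z = A*sin(pi*x/W)`.
  With `W` fixed the amplitude has the closed-form projection solution.
  With `W` free the amplitude is profiled out (linear given `W`) and the
  profiled residual sum of squares is scanned over `[0.5, 3]` times the
  x-range before Brent refinement — the profiled objective is oscillatory,
  and the scan avoids spurious high-frequency minima that a single local
  search from one starting value can fall into. A damped Gauss-Newton
  polish then drives both parameters to machine precision, which is what
  makes exact (zero-residual) inputs such as the three landmark points
  `(0,0)`, `(W/2, h)`, `(W,0)` recover `A` and `W` to 1e-12. Degenerate
  inputs error out: fewer than 3 points, zero x-range, or all-zero heights
  with `W` free (with `W` fixed the all-zero case is well posed and gives
  `A = 0`).
* **Meshing.** The structured `(theta, zfrac)` grid collapses to a point at
  each commissure, where the free-edge height vanishes. Coincident vertices
  (within 1e-9 mm) are merged and the resulting zero-area triangles
  removed, so exported meshes contain no degenerate faces. Faces are wound
  so normals point radially outward. Triangle-area quadrature of the mesh
  converges to the closed-form area at second order in the angular
  resolution; the package's oracle tests measure the empirical order over
  refinement doublings from 128x64 up to 1024x512 and check agreement with
  an independent 1-D adaptive quadrature of the flattened boundary
  (`flat_area_quadrature()`), exploiting developability.
* **Mesh formats.** In memory, faces are 1-based index triples (the R
  convention). On disk each format keeps its own convention: OBJ 1-based
  indices, PLY and legacy VTK 0-based, STL an unindexed triangle soup
  (binary STL stores float32, so round trips are exact only to single
  precision). Writers go through a temporary file renamed into place, so a
  failure never leaves a partial file.

## The synthetic cohort generator

`sample_cohort()` draws per-cusp (width, height) pairs from independent
normal distributions with the published per-cusp means and SDs, truncated
at zero by resampling; `sample_boundary_points()` produces flattened
free-edge point clouds with uniform abscissae and additive Gaussian noise.
These defaults are the study conditions for the package's statistical
tests: amplitude recovery uses 500 replicates of 500-point clouds at 0.2 mm
noise, and cohort sanity uses 10,000 samples per cusp.

The generator emulates *measurement scatter around the idealized model*,
not real anatomy: real cusps are asymmetric, their free edges deviate from
a sine, width and height are likely correlated, and measurement error is
not homoscedastic Gaussian. Passing the recovery tests therefore shows that
the fitting and measurement pipeline is correct and well calibrated under
the model's own assumptions — it does not validate the cylindrical-shell
idealization against real valves. Only the comparison of derived metrics
with published cadaveric statistics (`compare_to_reference()`) touches real
data, and that comparison is descriptive (z-scores), not inferential.

## Known limitations

* Purely geometric: no material properties, stress–strain analysis,
  external force fields, or valve closure dynamics.
* The fully open configuration only; no attempt to model pathological
  valves (stenosis, distorted lobular edges).
* The assembled valve is an open surface — no annulus cap or sinus walls.
* Exact n-fold symmetry and identical cusps; per-cusp variation enters only
  through the synthetic cohort, one cusp geometry at a time.
* The closed-form cusp area for the default instance (182.7075 mm^2)
  differs by about 0.05% from the commonly quoted 182.6220 mm^2, which
  appears to stem from an unstated coarse discretization; the package
  reports the exact integral as canonical and provides the quadrature path
  (`cusp_area_quadrature()`) for studying discretization effects.
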