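---
title: "Ephaptic modulation indices on cortical surface meshes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ephaptic modulation indices on cortical surface meshes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emod)
```

## The model

Synchronized pyramidal-cell populations behave as current dipoles oriented
along the local cortical surface normal, and — by the same antenna-like
geometry — as receivers of quasi-static extracellular fields. In a
homogeneous medium of conductivity $\sigma$, a point current dipole
$\mathbf p$ produces

$$\mathbf E(\mathbf x) \;=\; \frac{1}{4\pi\sigma r^{3}}
  \left(3(\mathbf p\cdot\hat{\mathbf r})\hat{\mathbf r}-\mathbf p\right),$$

which `dipole_field()` evaluates (with the matching potential
$\Phi = \mathbf p\cdot\hat{\mathbf r}/4\pi\sigma r^{2}$ in
`dipole_potential()`). The membrane perturbation of an elongated neuron
with effective space-constant vector $\boldsymbol\lambda$ in a locally
uniform field is, to first order, $\delta\Phi=\boldsymbol\lambda\cdot
\mathbf E$ (the lambda-E rule, `lambda_e()`): millimetre space constants
times fields of order 0.1 V/m give perturbations of order 100 μV.

Writing the source at surface vertex $y$ as $\mathbf p_y = p_0\,\delta
A\,\mathbf n_y$ and the receiver as $\boldsymbol\lambda_x = \lambda_0
\mathbf n_x$, the impact of $y$ on $x$ with the receiver on the dipole
axis collapses to a signed inverse-cube kernel with prefactor
$\kappa=\lambda_0 p_0/2\pi\sigma$. The per-vertex index is the gated pair
sum

$$\varepsilon_1(x) \;=\; -\kappa\sum_{y\neq x}
  \Theta[-\mathbf n_x\cdot\mathbf n_y]\;\Theta[l_0-r]\;
  \frac{\mathbf n_x\cdot\mathbf n_y}{r^{3}}\;(\delta A_y),$$

and the global index is its mean over valid vertices. The orientation
gate keeps only pairs whose normals oppose — facing sulcal walls — and the
distance gate keeps only pairs within the temporal-coherence radius
$l_0$. Both gates are strict ($\Theta[x]=0$ for $x\le 0$): a pair at
exactly $r=l_0$, or with exactly orthogonal normals, contributes nothing.
The minus sign makes gated contributions nonnegative (opposing normals
have $\mathbf n_x\cdot\mathbf n_y<0$).

## Parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `lambda0` | 1 | mm | effective neural space constant of the receiver population |
| `p0` | 0.5 | nA·m/mm² | dipole surface density of coherent cortical activity |
| `sigma` | 0.40 | S/m | grey-matter conductivity (see `tissue_conductivities()`) |
| `l0` | 5 | mm | maximal distance for temporally coherent interaction |

The derived prefactor is $\kappa = 198.94$ μV·mm at the defaults (with
`r` in mm and areas in mm²). Dipole densities of 0.5–1.0 nA·m/mm² bracket
measured neocortical values; a 60 mm² patch discretized as 77 grid
dipoles then carries 0.39–0.78 nA·m per dipole (`make_grid_patch()`).

## Units and the `use_area` convention

With `use_area = TRUE` the source vertex area $\delta A_y$ (mm²) enters
each term and the map is in μV; an interior vertex between parallel
plates at separation $d<l_0$ then approaches the closed-form disc
integral $2\pi\kappa(1/d - 1/l_0)$ — about 250 μV at $d=2.5$ mm — which
the test suite verifies to 2%. With `use_area = FALSE` (the default,
matching how the published cortical maps were computed) the bare
$\Sigma\,1/r^3$ carries mm⁻³ and the map is reported in model units of
μV·mm⁻²; this convention weights densely triangulated (high-curvature,
sulcal) regions more strongly, and the absolute scale depends on mesh
density (halving the edge length roughly quadruples the bare sum, a
sensitivity the tests document). Every result records its convention in
`meta$units`.

$\delta A$ attaches to the *source* vertex because the area enters
through the source dipole moment $\mathbf p_y=p_0\,\delta A\,\mathbf
n_y$, not through the receiver.

## Numerical choices

* **Pair search.** `neighbors_within()` uses a uniform-grid spatial index
  and then recomputes the surviving distances with the same elementwise
  expression as the all-pairs scan, so the pair set and distances are
  bit-identical to `neighbors_brute_force()`. Pairs closer than $10^{-6}$
  mm are excluded to guard $1/r^3$ against merged-vertex residue.
* **Summation order.** Contributions accumulate in ascending neighbor
  index; `emod_local()` and the independent `emod_brute_force()` oracle
  agree to $10^{-9}$ relative on every phantom.
* **Pair-list integrity.** `emod_local()` refuses a pair list built with
  a different `l0` than its parameters: truncating (or silently missing)
  pairs would corrupt the sum.
* **Vertex frames.** Vertex normals are area-weighted averages of
  incident face normals (stable on irregular triangulations, though only
  first-order accurate: a radius-1 icosphere needs ~160k vertices before
  every normal is within $10^{-3}$ of radial); vertex areas are one third
  of incident face areas, so they conserve total surface area exactly.
  Vertices with no incident face are masked invalid.
* **Orientation.** `repair_mesh()` makes winding consistent by
  propagation across shared edges and orients closed meshes outward by
  the signed-volume test; open meshes keep their winding orientation
  (with a warning if outward orientation was requested). The index itself
  is invariant under a global normal flip, so the residual ambiguity on
  open surfaces is harmless for EMOD1.
* **Geodesics.** Dijkstra on the mesh edge graph (via igraph). Edge-graph
  distances are anisotropic on structured grids — up to $\sqrt2$ along
  directions the triangulation does not resolve — so planar-limit checks
  compare along grid axes and diagonals only. Smoothing
  (`smooth_map()`) uses a geodesic Gaussian truncated at $3\sigma$ with
  per-vertex weight renormalization; the delta-response half-maximum
  lands within 15% of FWHM/2 on a fine flat grid.
* **Degenerate inputs.** Empty meshes, unrepairable meshes, singular
  observation points, sign-mixed decay fits, constant covariates and
  out-of-range sources all raise errors rather than returning quietly
  wrong numbers.

## Index variants

`EMOD1` (both gates, signed kernel) is fully specified. `EMOD0` and
`EMOD1a` appear in the variant registry but their defining support
functions are not published; `emod_variant("EMOD0", ...)` therefore
*requires* the caller to state gates or a custom weight — the package
invents no default formula for them.

## What the phantoms emulate — and what they do not

`make_sulcus_phantom()` builds an open surface: two planar walls at a
controllable wall-to-wall `width`, a semicylindrical fundus, optional
outward gyral crowns, extruded to a ridge of controllable `length`. It
reproduces the one geometric feature the index is designed around —
facing, oppositely oriented cortical walls a few millimetres apart — with
exactly known parameters: facing wall vertices sit `width` apart with
anti-parallel normals, so the deep-wall index approaches the
parallel-plate closed form (verified to 5%).

It does not emulate: curvature-dependent field enhancement, variable
mesh density of real reconstructions (phantom triangles are near
uniform), tissue heterogeneity (CSF in the sulcal gap raises real fields
above the homogeneous-medium surrogate), cortical thickness variation,
or the global folding pattern of a hemisphere. Passing tests on phantoms
therefore validate the *computation* of the index and its geometric
response to sulcal width — not the physiological magnitude of ephaptic
coupling in vivo, which inherits every limitation of the simplified
kernel (the published analysis shares this caveat: the index is an
approximation, not a full field calculation).

The field physics itself is an analytic infinite-homogeneous-medium
surrogate (grey-matter conductivity by default). It reproduces the
$r^{-3}$ single-source decay regime that the reference finite-element
solves fit (−3.02 in the toy sulcus model against the analytic −3.000)
and the ≥0.1 V/m opposite-wall magnitude at 1 mm for the 1.0 nA·m/mm²
patch, but no skull/CSF boundary effects.

## The synthetic cohort

`make_synthetic_cohort()` draws subject ages uniformly over 16–83 years
and sulcal widths from $w(\mathrm{age}) = 0.8 + 0.03\,\mathrm{age} +
\mathcal N(0, 0.15)$ mm, clamped at 0.3 mm (median sulcal widths across
the adult span range roughly 0.5–5 mm, and widen with age). These
defaults are artifact choices emulating reported widening, not measured
claims. All subjects share one mesh topology (fixed `segments`), so
vertex-wise group statistics need no registration step — the phantom
stand-in for the spherical-registration correspondence that real cohort
pipelines provide. The generator is a pure function of its spec; the
same seed reproduces the cohort byte for byte.

Because the index decreases monotonically with width (the $1/d$ plate
law) and width rises with age, the cohort shows a negative EMOD1–age
correlation. The parameter-recovery check runs 20 replicates of an
n = 40 cohort and requires a negative global correlation with a
majority of vertices BH-significant at $q=0.05$ in at least 95% of
replicates — it passes 20/20 at the defaults.

## Morphometric proxies

* `vertex_thickness()` is the corresponding-vertex distance between a
  white and a pial surface — a deliberate simplification of the symmetric
  definition used by full pipelines, exact on the concentric and parallel
  geometries it is tested on.
* `gyrification_proxy()` uses the convex hull as the outer envelope.
  Two adaptations make this behave on our inputs: (1) for *open* meshes
  the hull is restricted to its upper side (faces whose outward normal
  agrees with the patch's mean orientation), because a full hull also
  wraps beneath an isolated fold, which no outer envelope of a closed
  cortex does; (2) area-within-radius sums use a linear partial-coverage
  ramp half an edge wide at the ROI boundary, removing the
  boundary-cell jitter of a hard cutoff on coarse meshes. The proxy is
  ~1 on spheres and sheets and rises above 2.5 at the fundus of a deep
  phantom sulcus — monotone in folding, though not numerically equal to
  a morphological-closing gyrification index.
* Statistics follow the standard pipeline: vertex-wise Pearson r with
  two-sided Student-t p-values ($t=r\sqrt{(n-2)/(1-r^2)}$),
  Benjamini–Hochberg step-up at $q=0.05$ (cross-checked against
  brute-force enumeration), and raw-polynomial OLS trend fits. Global
  metrics are computed unsmoothed; smoothing is for vertex-wise maps.

## Problem sizes

The test and acceptance runs use phantoms of a few hundred to two
thousand vertices — large enough that interior vertices reach the
continuum closed forms to the stated tolerances, and small enough that
the quadratic brute-force oracle remains an exact cross-check. The
cohort stage uses 40 subjects of ~400 vertices each over 20 replicates.

## Known limitations

Homogeneous-medium physics only; no FEM, no realistic head geometry, no
spherical registration; the EMOD0/EMOD1a formulas are deliberately left
unspecified; the bare-sum (`use_area = FALSE`) scale is mesh-density
dependent and only comparable across meshes of similar resolution; the
gyrification proxy's outer surface is a hull, not a closing wrap.
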