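---
title: "Finite-deformation elastography by inverse FE topology optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finite-deformation elastography by inverse FE topology optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdelast)
```

## The problem

Stiff, thin soft tissues — articular cartilage is the motivating example —
are hard to probe with shear-wave elastography: the wave frequencies needed
to resolve sub-millimetre structure attenuate too quickly in stiff material.
An alternative is to image finite deformations directly. Cyclic mechanical
loading synchronized with displacement-encoded MRI (DENSE-type sequences)
yields phase maps whose phase is proportional to tissue displacement,

$$\Delta\varphi \;=\; \gamma_H\, t_{\mathrm{enc}}\, (G_{\mathrm{de}} -
G'_{\mathrm{de}})\, \Delta x ,$$

so a wrapped phase map, an unwrapping step and a smoothing step produce a
displacement field at pixel resolution. `fdelast` reconstructs a spatial map
of *relative stiffness* from such a field.

## The inverse model

The tissue is modelled as isotropic linear-elastic (plane stress in 2D,
full law in 3D) with near-incompressible Poisson's ratio $\nu = 0.49$: the
loading ramps are fast relative to fluid flow time scales, so the solid
behaves nearly incompressibly. Each finite element $k$ carries a relative
density $\rho_k$ that scales a baseline modulus,

$$E_k = \rho_k^{\,p}\,E^0, \qquad 0 < \rho_{\min} < \rho_k \le 1,$$

the density parameterization of topology optimization (SIMP). The exponent
is $p = 1$: no void/solid penalization is wanted here, so stiffness is
linear in density and the converged density map *is* the relative-stiffness
map. Because all boundary conditions are prescribed displacements, the
absolute scale $E^0$ is unidentifiable — any uniform rescaling of the map
produces identical displacements — and $E^0 = 500$ Pa is an arbitrary
convention. Maps are reported after rescaling to mean relative stiffness
0.5 ([normalize_relative_stiffness()]), which preserves all region ratios.

The measured field enters twice. Its values at mesh boundary nodes become
Dirichlet data (every boundary node is prescribed in the inversion); its
values at internal nodes $P_i$ are the targets of the design objective

$$F \;=\; \min \; \max_{i=1}^{N} \big( w_i\,\lvert \Delta x_{\exp}(P_i) -
\Delta x_{\mathrm{sim}}(P_i) \rvert \big),$$

the worst-case weighted mismatch between measured and simulated
displacement. Weights $w_i$ default to 1; [weight_outliers()] can down-vote
pixels whose residual against the smoothed field is large.

## Numerical treatment

**Smooth surrogate.** The max-norm is not differentiable, so gradients are
taken on a $p$-norm aggregation $\tilde F = (\sum_i a_i^{q})^{1/q}$,
$a_i = w_i\lvert r_i\rvert$, with $q = 12$ by default — a standard
bound-formulation surrogate that upper-bounds the true max and converges to
it as $q$ grows. The true max is evaluated and reported at every iterate.
Smaller $q$ behaves like least squares; in our Monte-Carlo experiments it
fit noise more aggressively (both bias and replicate variance increased),
so the max-like default stands.

**Adjoint sensitivities.** With stiffness linear in $\rho$, one adjoint
solve per iteration gives the full sensitivity vector:
$K\lambda = \partial\tilde F/\partial u$ on the free DOFs, then
$\partial\tilde F/\partial\rho_k = -\lambda^{\mathsf T}
(\partial K/\partial\rho_k) u$ with
$\partial K/\partial\rho_k = p\rho_k^{p-1}E^0 K_k^{(1)}$. The adjoint
reuses the forward factorization, so each iteration costs one sparse
Cholesky factorization (supernodal, with symbolic analysis and the
assembly-aggregation operator cached across iterations) plus two triangular
solves. Gradients are verified against central finite differences to
better than $10^{-5}$ relative in the test suite.

**Sensitivity filtering.** Element sensitivities are averaged with
cone-shaped (linear-decay) weights over a radius of twice the element size
by default, normalized per element. Filtering regularizes the inverse
problem and keeps reconstructions mesh-independent. For the coarse 3D
cylinder mesh (0.6 mm elements against layers only 2–6.7 elements thick)
the validation runs use 1.5 times the element size instead, so the kernel
footprint stays small relative to the layers being resolved; the
edge-artifact remedy for corrupted data multiplies the radius by a
configurable factor in the opposite direction.

**Density update.** The default update is the method of moving asymptotes:
each iteration minimizes a separable convex approximation of the surrogate
whose per-element asymptotes widen or tighten depending on whether the
element's density is moving monotonically or oscillating. With only box
constraints ($\rho \in [\rho_{\min}, 1]$, per-iteration move limit 0.1)
the MMA subproblem has a closed-form elementwise solution, so no inner dual
iteration is needed. Every step is accepted only if it reduces the
surrogate (backtracking shrinks the move limit and asymptotes otherwise),
making the accepted-objective trace non-increasing by construction. A
projected spectral-gradient (Barzilai–Borwein) rule is available as
`optimizer = "pg"`; it is markedly slower on badly scaled problems, which
is why MMA is the default and the field standard.

**Initialisation, stopping, degeneracies.** Densities start uniform at
0.5, $\rho_{\min} = 0.01$, at most 100 iterations by default; convergence
is declared after 5 consecutive iterations with relative surrogate change
below $10^{-4}$, or when no admissible step descends (first-order
stationarity at line-search resolution). Noise-free 3D runs use a
300-iteration budget — the coarse-mesh problem converges more slowly. If
data are symmetric enough that two layer assignments fit equally well,
both the map and its ratios are reported without injecting symmetry
breaking. An optional density-smoothness penalty
(`smoothness_weight`, default 0) ties data-unconstrained elements to their
neighbourhood; the validation phantoms do not need it.

## Preprocessing choices

*Phase unwrapping* is quality-guided flood fill: pixels are visited in
order of local phase smoothness and offset by the 2π multiple that makes
them consistent with their already-unwrapped neighbour. Disconnected mask
components are unwrapped independently (their mutual offsets are
unidentifiable) with a warning. A congruent least-squares unwrapper was
considered and not needed for the validation suite: flood fill is exact on
wrap-free fields and on smoothly varying fields at these noise levels.

*Smoothing* defaults to robust LOWESS: a local linear fit over the 150
nearest masked pixels (the window size used for displacement-encoded MRI
regions of interest) with tricube distance weights and three bisquare
reweighting passes, which approximates least-absolute-residual fitting.
The window is interpreted as a pixel *count*, not a per-axis span — on an
anisotropic grid the window follows physical distance. Mask-normalized
Gaussian smoothing is provided for comparison; its one-sided averages
flatten genuine gradients at thin-mask edges, which is exactly the bias
the robust local fit avoids, and the factor screening reproduces this
difference.

*Noise model*: independent zero-mean Gaussian perturbation (default SD
0.1 mm, the experimental displacement noise level) on every masked pixel,
boundary pixels included, since measured boundary data are no cleaner than
interior data.

## Meshing

Meshes are built directly on the pixel lattice: nodes at pixel corners,
one bilinear quad (trilinear hex in 3D) per masked pixel, optionally
coarsened to a target element size (0.6 mm is the usual working density;
validation uses the native 0.15 mm to match the imaging resolution). The
simplicial families split each lattice cell along its diagonal — a valid
Delaunay triangulation of the regular lattice — and cull slivers shorter
than the minimum-feature threshold (0.5 mm, capped at the element size).
Boundary nodes are detected topologically as nodes on facets owned by a
single element. Bilinear/trilinear grid-to-mesh interpolation is exact for
affine fields and verified against a brute-force oracle.

## What the phantoms emulate — and what they do not

The phantom module generates every validation input: the 6 × 6 mm bilayer
(1000 Pa over 500 Pa, 15% indentation, 0.15 mm pixels), stiff circular
inclusions (1000/1500 Pa on 500 Pa), a soft slender fissure-like inclusion
(200 Pa) on a 500→1000 Pa gradient, a 3D two-layer cylinder (radius 5 mm,
height 6 mm, top third stiff, 2:1 ratio, 0.6 mm voxels — the cylinder
geometry mirrors the 10 mm diameter, 6 mm tall gel implants), and a
homogeneous null case. Loading is displacement-controlled indentation with
the base fixed and the platen adhered (lateral surfaces free). Inclusion
positions and the non-bilayer 2D resolutions (0.2 mm) are package defaults
chosen to keep desk-scale runs light.

Synthetic displacements are forward-solved on the same element family used
for inversion, so phantom studies quantify the error of the *inversion
pipeline* (noise, smoothing, optimization), not modelling error against
real tissue: geometric nonlinearity at 15% strain, constitutive
nonlinearity, through-plane effects in 2D slices, and MRI artifacts other
than additive Gaussian noise are outside what passing tests demonstrate.

## Error analysis

[monte_carlo()] repeats noise → LOWESS → inversion → normalization, and
summarizes per-element replicate statistics: **bias** is the RMS of the
replicate-mean map minus the normalized truth; **precision** is the pooled
(RMS over elements) across-replicate SD. The wording of the reference
definition is ambiguous about pooling, so the per-replicate-RMSE variants
are recorded alongside (`bias_per_replicate`, `precision_rmse_sd`).
Desk-scale runs use 30 replicates; the reference study used 100.

[cotter_sensitivity()] implements the systematic fractional two-level
design: $2m{+}2$ runs for $m$ factors (all-low, each-singly-high,
each-singly-low, all-high), odd/even contrasts per factor and importance
$M = |C_o| + |C_e|$, which on an additive response is exactly half the
absolute effect coefficient. The default pipeline factor grid spans noise
SD (0.02/0.2 mm), smoothing technique (LOWESS/Gaussian), Poisson's ratio
(0.3/0.49), filter radius (1×/4× element size), mesh density (0.3/0.6 mm)
and iteration budget (30/100). Constitutive-law and 2D-assumption factors
from the original screening involve hyperelastic models that are out of
scope here.

## Known limitations

- Only relative stiffness is identifiable; absolute calibration would need
  force/stress boundary data, which the formulation does not include.
- The displacement formulation at $\nu = 0.49$ is adequate for these
  accuracy targets but will lock as $\nu \to 0.5$ in 3D; no mixed or
  selective-reduced formulation is implemented.
- Elements adjacent to fully prescribed boundaries are weakly observable;
  their values rely on the sensitivity filter (and optionally the
  smoothness penalty) rather than on data.
- Monte-Carlo replicate variance is sensitive to the optimizer's effective
  regularization. With the defaults above the 30-replicate bilayer
  experiment lands at a *less biased, more variant* operating point than
  the reference implementation (bias ≈ 0.056 vs 0.092; pooled
  across-replicate SD ≈ 0.14 vs 0.066) — the usual regularization
  trade-off. The reference optimizer's internal constraints are not
  published, and within the exposed parameters no setting reproduces its
  variance without inflating bias, so the validation suite reports the
  measured values rather than retuning toward the published ones.

## Problem sizes used in the shipped analyses

The bilayer Monte-Carlo experiment runs 30 replicates of the full 40 × 40
element (0.15 mm) model; the 3D cylinder runs a single 2160-hexahedron
inversion with a 300-iteration budget; the remaining property checks use
6–900-element models. These sizes were chosen so the whole validation
suite runs comfortably on one CPU core.
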