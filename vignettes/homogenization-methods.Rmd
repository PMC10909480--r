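---
title: "Homogenization of glandular tissue microstructures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homogenization of glandular tissue microstructures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HistoMech)
```

## The problem

Normal prostate (and similar glandular) tissue is a three-phase composite:
a fibromuscular **stroma** rich in collagen, **epithelial compartments**
lining the glands, and fluid-filled **acinar lumens**. Its apparent
stiffness is anisotropic and markedly different in tension and compression,
because collagen fibres stiffen the stroma only when stretched along their
local direction. HistoMech computes apparent (homogenized) anisotropic
moduli of such tissue from a segmented two-dimensional microstructure
image, and provides the surrounding analytics: fabric-tensor anisotropy,
fibre-orientation mapping, and parametric study drivers.

The pipeline mirrors the histology-based workflow:

1. a segmented three-phase label raster (or the built-in synthetic
   generator standing in for real regions of interest);
2. structure-tensor estimation of local collagen orientation in the stroma;
3. mean-intercept-length (MIL) fabric analysis, rotation of the image into
   its fabric principal directions, a centred square crop, and a re-check
   that the residual principal angle stays within 2 degrees;
4. mirroring of the aligned square into a perfectly orthotropic, exactly
   periodic cell;
5. pixel-based plane-stress finite-element homogenization under periodic
   boundary conditions for six load cases (uniaxial tension/compression in
   both directions, positive/negative shear), giving six secant moduli.

## Constitutive models

All constituents are modelled as nearly incompressible hyperelastic solids
(units kPa). The epithelial compartment and the acinar lumen use a
compressible neo-Hookean energy

$$\Psi_{NH} = C_{10}(\bar I_1 - 3) + \tfrac{1}{D_1}(J-1)^2,$$

with $\bar I_1 = J^{-2/3}\,\mathrm{tr}\,C$ and $J$ the volume ratio. The
stroma uses the Holzapfel–Gasser–Ogden (HGO) form with a single collagen
fibre family,

$$\Psi = \Psi_{NH} + \frac{k_1}{2k_2}\left[e^{k_2 E^2} - 1\right],
\qquad E = \kappa(\bar I_1 - 3) + (1 - 3\kappa)(\bar I_4 - 1),$$

where $\bar I_4$ is the squared distortional stretch along the fibre
direction, $k_1$ (kPa) the fibre stiffness, $k_2$ the dimensionless
nonlinearity and $\kappa \in [0, 1/3]$ the in-family dispersion. The fibre
term is active only when $E > 0$: fibres carry no load when the matrix is
compressed along them, which is the mechanism behind the
tension–compression asymmetry. The energy is $C^1$ across the switch (the
fibre term is $O(E^2)$), so the tangent jump there is benign; the branch is
decided on the sign of $E$, which for $\kappa = 0$ coincides with
$\bar I_4 < 1$.

Dispersion within an orientation sub-region is not modelled
($\kappa = 0$ for stroma by default); dispersion at the tissue scale is
carried by window-to-window variation of the local fibre angle, which is
how the per-element orientation map enters the model.

### Parameters and conversions

| Parameter | Constituent | Default / range | Units |
|---|---|---|---|
| $C_{10}$ stroma | HGO matrix | 5–30, benchmark 17.5 | kPa |
| $k_1$ | HGO fibres | 10–300, benchmark 155 | kPa |
| $k_2$ | HGO fibres | 200 | — |
| $\kappa$ | HGO fibres | 0 | — |
| $C_{10}$ epithelium | NH | 0.192–4.801, default $\sqrt{0.192 \cdot 4.801} \approx 0.96$ | kPa |
| $C_{10}$ lumen | NH | 1.92–192, default $\approx 19.2$ | kPa |
| $\nu$ (effective) | all | 0.49 | — |

Near-incompressibility is parameterized by an effective small-strain
Poisson ratio $\nu$ using $\mu_0 = 2C_{10}$ and $K_0 = 2/D_1$, giving
$D_1 = 3(1-2\nu)/(2C_{10}(1+\nu))$ (`d1FromNu()`). The small-strain
Young's modulus is $E_0 = 4C_{10}(1+\nu)$, which approaches $6C_{10}$ in
the incompressible limit — the package's small-strain validation check.
Published epithelial stiffness is usually a Young's modulus; the
conversion to $C_{10}$ depends on the assumed $\nu$ and is therefore an
explicit function (`youngsToC10(E, nu)`), not a hard-coded constant. The
literature band quoted above for the epithelium is used directly as the
$C_{10}$ sweep range. The defaults held fixed while sweeping another
constituent are the geometric mid-ranges of the bands, a deliberate
package choice where the source workflow does not state them.

## Plane stress and the condensed point response

The finite elements are two-dimensional; the out-of-plane stretch
$\lambda_3$ is a local (per quadrature point) unknown solved from
$\sigma_{33}(F_{2\times 2}, \lambda_3) = 0$ by a safeguarded scalar Newton
iteration (root bracketed in $[0.05, 20]$, tolerance
$|\sigma_{33}| < 10^{-10}\max(1\,\mathrm{kPa}, \lVert\sigma\rVert)$).
Because $\partial\Psi/\partial\lambda_3 = 0$ at the root, plane stress is a
partial minimization of the energy in $\lambda_3$, and the condensed
in-plane tangent is the Schur complement
$A = H_{FF} - H_{F\lambda} H_{\lambda\lambda}^{-1} H_{\lambda F}$ of the
analytic 5×5 energy Hessian. Both gradient and Hessian are analytic (no
internal differencing); the test suite checks them against central finite
differences of the energy at random admissible states.

A consequence worth noting: under plane stress the in-plane problem
carries **no volumetric constraint** — any in-plane deformation can be
accommodated at constant volume through the thickness. Bilinear
quadrilaterals therefore do not lock even at $\nu = 0.49$, and the solver
uses plain 2×2 Gauss quadrature rather than selective reduced integration;
the homogeneous-cell exactness checks (machine-precision agreement with
the pointwise response) confirm there is no parasitic stiffness to
suppress.

## Periodic homogenization

The mesh is structured: one bilinear quad per pixel (or per
`coarsen`×`coarsen` block, labels by majority vote with ties resolved
stroma > epithelium > lumen). Displacements are parameterized with the
affine/fluctuation split $u(X) = H X + \tilde u(X)$, where $H$ is the
macroscopic displacement gradient held in four reference DOFs and
$\tilde u$ is a periodic fluctuation shared between opposite-boundary node
pairs (each boundary node belongs to exactly one pairing; the origin
corner is pinned to remove rigid translation). This enforces
$u(x^+) - u(x^-) = H(x^+ - x^-)$ exactly and starts every Newton increment
from the correct affine state.

Load cases (global test strain 5 %, both signs):

* **uniaxial-1 / uniaxial-2**: the normal component of $H$ prescribed,
  macro shear zero, and the transverse normal component *free with zero
  conjugate macro force* — a uniaxial macro-stress test, so
  $\langle\sigma_{11}\rangle/\varepsilon$ is a Young's-type secant modulus
  comparable to indentation-derived stiffness. The alternative (fully
  prescribed macro strain) is available via `transverse = "fixed"`.
* **shear-12**: $H_{12} = H_{21} = \gamma/2$ prescribed (engineering shear
  $\gamma$, no macro rotation), normal components free.

Equilibrium is solved by incremental Newton–Raphson (default 5 increments,
25 iterations each, relative residual $10^{-10}$, automatic increment
halving on divergence, 3 levels). The volume-averaged Cauchy stress is
$\langle\sigma\rangle = \sum_q w_q P F^\top / \sum_q w_q J$, and the macro
reactions at the $H$ DOFs equal $V_0 \bar P$; the Hill–Mandel identity
$\langle P F^\top\rangle = \bar P \bar F^\top$ is recomputed for every
converged solve and reported as a relative consistency error (of order the
solver tolerance). Secant moduli are taken at the full test strain:
$E_{11} = \langle\sigma_{11}\rangle / 0.05$, compression with the absolute
value, $G_{12} = \langle\sigma_{12}\rangle / \gamma$.

The RVE-size logic (`rveConvergenceStudy`) crops growing pre-mirror
windows, mirrors each, and declares convergence at the smallest size
beyond which all six moduli and the area fractions change by less than 2 %
between consecutive sizes. Mirroring doubles the final cell; "RVE size"
always refers to the pre-mirror window.

## Fabric tensor and orientation analytics

**MIL.** For each of `nDirections` (default 180) sampling directions —
uniformly spaced with one shared random offset drawn from the seed —
parallel lines at 1 px spacing are laid over the mask, and
MIL($\theta$) = total foreground length / number of foreground runs
(run-based convention, interfaces at label transitions). Grid sampling of
oblique lines fragments single intercepts along staircase pixel
boundaries; background gaps shorter than 1.25 px therefore do not split a
run, which removes a ~30 % spurious anisotropy observed on a perfect disk
(to ~4 % residual). The cloud of MIL vectors (with antipodes) is fitted by
an origin-centred ellipse via linear least squares on $x^\top Q x = 1$ —
the antipodal symmetry makes the centred 3-parameter fit exact and avoids
the instability of a general 5-parameter conic. Radii $a \le b$ come from
the eigenvalues of $Q$; the degree of anisotropy is $DA = 1 - a^2/b^2$
($0$ isotropic, $1$ fully anisotropic; a collinear cloud degenerates to
$a = 0$, $DA = 1$). After rotating an image into its principal directions
and cropping, the fabric analysis is repeated and the residual principal
angle must stay within the 2-degree allowance; fabric with
$DA \le 0.05$ is treated as isotropic and passes with a note, since its
principal direction is not meaningful.

**Orientation.** Local fibre direction is estimated per non-overlapping
window (default 32 px, chosen well below typical stromal channel lengths)
from the gradient structure tensor of the Gaussian-smoothed
(default $\sigma = 1.5$ px) stroma indicator, using Scharr-weighted
gradients for rotational accuracy and accumulating only over the window's
stromal pixels. The channel direction is the eigenvector of the smaller
eigenvalue; coherence is
$(\lambda_{max}-\lambda_{min})/(\lambda_{max}+\lambda_{min})$ with $0/0
\mapsto 0$. Windows with under 25 % stroma inherit the nearest valid
window's angle (ties by row-major order) so that every stromal element can
be assigned an angle. All angles are axial, in degrees, counter-clockwise
from the x-axis, folded to $[-90, 90)$; reflections map
$\theta \mapsto -\theta$, which is how the orientation map transforms
under mirroring.

## The synthetic generator

Real regions of interest behind the original workflow are not publicly
available, so the package generates seeded three-phase microstructures
that emulate their statistical structure: elliptical acini (lumen core
plus epithelial ring of fixed thickness) placed by dart throwing (hard
non-overlap via support-function separation, at most $10^4$ attempts per
acinus, failure is an explicit error) in a connected stromal matrix, with
controllable area fractions, acinus elongation, preferred orientation and
orientation dispersion. Default geometry (256 px at 4 µm/px, 16 acini of
~40 µm lumen radius with a 46 µm epithelial ring) gives area fractions of
roughly stroma 0.55, epithelium 0.33, lumen 0.12.

What the generator does **not** emulate: acinar branching and ductal
connectivity, stain texture and colour, basal/luminal cell substructure,
and — because random sequential placement of hard ellipses jams near ~50 %
packing — cohorts in which the epithelial fraction exceeds the stromal
fraction, as dense real prostate fields can. Tests passing on synthetic
cohorts therefore demonstrate correctness of the mechanics and analytics
pipeline and qualitative structure–property trends, not quantitative
agreement with any particular histology dataset; accordingly the
real-data regression strengths and DA values of the source workflow are
not reproduction targets.

## Numerical choices and degenerate inputs

* Newton tolerances as above; the tight residual makes the Hill–Mandel
  check meaningful at $10^{-8}$.
* $\lambda_3$ warm starts are cached per quadrature point across
  iterations and increments.
* Label rotation uses nearest-neighbour sampling (labels are categorical;
  interpolation inventing labels would be a defect); exact multiples of
  90° are performed as exact raster rotations.
* Ellipse-fit degeneracies: rank-deficient clouds return $a = 0$ with the
  major axis along the points; $a = b$ returns angle 0 flagged arbitrary.
* Empty-foreground masks are errors; full-foreground masks return the
  mean chord length flagged degenerate (zero interfaces, one run per
  line).
* Thresholding bands are fixed dark-to-bright as epithelium / stroma /
  lumen, matching H&E appearance; thresholds themselves are user
  parameters.
* Problem sizes used by the shipped studies and tests: quadrants of
  32–176 px meshed at 16–64 elements per side, cohorts of 8 RVEs, the
  5×5 stromal factorial on a mirrored 32×32-element cell. These sizes give
  mesh-converged qualitative behaviour for the smooth synthetic
  geometries while keeping a full run on a single CPU in minutes;
  `coarsen` exposes the mesh-density control to the user.

## Known limitations

* Two-dimensional plane-stress idealization; no viscoelasticity, damage,
  or contact; strains validated only in the ±5 % regime.
* A single fibre family per point with $\kappa \le 1/3$.
* The acinar lumen is modelled as a soft neo-Hookean solid, not a fluid
  cavity.
* The uniaxial transverse condition of the source workflow is not
  documented there; uniaxial macro stress is the default here and the
  fully prescribed variant is a switch (moduli differ by a Poisson
  factor).
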