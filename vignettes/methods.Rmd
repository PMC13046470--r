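---
title: "Boundary-induced polar order: model, measurements and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boundary-induced polar order: model, measurements and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the confined polar-fluid model, the 3D orientation measurements, the
material-parameter inference, and the numerical and design decisions made
where more than one reasonable choice existed.

## The confined polar fluid

The tissue is modelled as a polar fluid in an axisymmetric domain bounded
by two spherical caps: the alpha cap (the interface with the
extraembryonic ectoderm, polar angles $\theta \in [0, \pi/2]$) and the
beta cap (the visceral-endoderm interface, $\theta \in [\pi/2, \pi]$),
joined continuously at the equator. Each cap has radius $R_\mu$ and an
axial centre offset $C_\mu$, giving the profile
$r(\theta) = C_\mu \cos\theta + \sqrt{R_\mu^2 - C_\mu^2 \sin^2\theta}$
(equivalently the curvature/offset-reciprocal form in `cap_radius()`).
Internally the package parameterizes caps by $(R_\mu, C_\mu)$ rather than
their reciprocals so that caps centred at the origin ($C = 0$, a perfectly
legitimate geometry) carry no singular parameter.

The local cell polarity is a vector order parameter $\mathbf p(\mathbf r)$
minimizing, in units of the characteristic length
$R_0 = (3V_0/4\pi)^{1/3}$ and the energy scale $F_0 = aR_0^3/2$,

$$\frac{F}{F_0} = \int_{\Omega'} \!\! dV' \Big[ |\mathbf p|^2 +
  \Big(\frac{\xi}{R_0}\Big)^2 \big( (\nabla\!\cdot\!\mathbf p)^2 +
  K\,[\hat{\mathbf p} \times (\nabla\!\times\!\mathbf p)]^2 \big) \Big]
  + \int_{\partial\Omega'} \!\! dS' \frac{\lambda}{R_0}
  (\mathbf p - \mathbf p_0)^2 .$$

The system is assumed isotropic in the bulk (the restoring term
$|\mathbf p|^2$ has a positive coefficient), so any order is induced by the
boundary anchoring. The tunable parameters are:

* $\xi/R_0$ — correlation length over tissue size (dimensionless,
  default scan 0.05–1). It sets how far boundary-imposed alignment
  penetrates the bulk.
* $\lambda/R_0$ — anchoring length over tissue size (dimensionless,
  default scan 0.1–20). Large values mean the boundary term dominates.
* $K = k_2/k_0$ — bend/splay modulus ratio, fixed at $10^{-2}$ throughout
  (splay-dominated distortions).
* $|\mathbf p_0| = 1$ — the preferred boundary magnitude; only the scale
  of $\mathbf p$ depends on it.

### Anchoring directions

The boundary rules are tangential on the alpha cap and normal on the beta
cap. Their orientations are not dictated by the energy alone, so the
package fixes a convention and exposes sign flags: the beta-cap
$\mathbf p_0$ is the *inward* unit normal (basal at the boundary, apical
toward the interior, consistent with apico-basal cell polarity), and the
alpha-cap $\mathbf p_0$ is the meridional tangent oriented *from the
equator toward the alpha apex*. This relative orientation was verified
numerically to be the one whose surface-dominated minimizer carries net
interior topological charge +1 — the configuration in which a single
aster-like singularity (the predicted lumen nucleation site) appears;
flipping one sign yields charge-0 fields. Both rules and signs are
configurable in `anchoring_spec()`, and a uniform perpendicular-anchoring
configuration serves as the control for defect-position comparisons.

## The finite-element minimizer

Because the problem is axisymmetric and twist-free, the energy reduces to
the meridional half-plane with the cylindrical measure $2\pi x\,dx\,dz$,
and the bend term collapses to the squared in-plane curl times
$|\mathbf p|^2/(|\mathbf p|^2+\epsilon^2)$ with $\epsilon = 10^{-6}$
regularizing $\hat{\mathbf p}$ at field zeros. The mesh is structured in
polar coordinates (angle columns and radial-fraction rings with a fan at
the origin, default edge length 0.05 $R_0$, an even column count so a node
sits exactly on the equator where the cap tags switch), and the field is
discretized with P1 triangles; $p_x = 0$ is imposed on the symmetry axis,
which is the regularity condition for axisymmetric vector fields. Interior
quadrature points keep the $p_x/x$ splay contribution finite on
axis-adjacent triangles.

The minimization lags the bend regularization factor between iterations,
solves the resulting sparse symmetric positive-definite system, and
backtracks on the true energy, so the energy trace is monotone; the
default start is the weak radial field $0.1\,(x, z)$ and solves may be
warm-started from neighbouring parameter values (phase diagrams and fit
grids do this along increasing $\lambda/R_0$), with optional
$\lambda$-continuation for cold starts in the stiff surface-dominated
corner. Convergence is declared at a relative step norm of $10^{-6}$.

Two numerical facts are worth recording. First, with uniform normal
anchoring the energy is second-order mesh-convergent (the test suite
checks the 0.05 vs 0.025 resolutions agree to 1%), whereas tangential
anchoring creates a surface *boojum* at the alpha apex — a genuine
boundary singularity where the preferred tangent is discontinuous across
the axis — and there the energy converges only at first order (checked to
5%). Second, the local field magnitude can exceed $|\mathbf p_0|$ near
that apex; this is a feature of the continuum solution, not an
instability.

### Defects

Topological defects are detected as connected clusters of interior nodes
whose $|\mathbf p|$ falls below 0.2 of the field maximum. Each cluster is
assigned the winding number of the direction field on loops around its
magnitude minimum, starting at three mesh spacings and growing
geometrically; a loop is only trusted when every sample is above a noise
floor and when adaptive bisection leaves no near-$\pi$ direction jumps
between samples (fixed sampling aliases the rapid flips near boojums by
whole turns). An isolated defect shows the same integer winding at every
informative radius; clusters with radius-dependent windings are not
isolated singularities and, if a single such cluster remains, its charge
is taken from the winding along the inward-offset domain boundary, which
equals the total enclosed charge. Zero-winding clusters — regions where
the order merely becomes small — are not defects. On-axis candidates use
the even/odd reflection $p_x(-x) = -p_x(x)$, $p_z(-x) = p_z(x)$.

Near the defect-free/defect-containing transition the zeros hover within
a mesh spacing of the boundary, and individual phase-diagram points there
can reclassify under discretization noise; the transition is therefore a
narrow band rather than a perfectly crisp line at desk-scale resolution,
and the property tests assert the band structure. One related caveat: when
the anchoring rules are swapped (tangential on the beta cap), the apex
boojum's near-boundary virtual charge can fall on either side of the
boundary-offset loop, shifting the reported total by one; defect
*positions* still mirror exactly in that configuration.

The reported defect position is $(z - c_L)/L$ with $L$ the axial extent
from the beta apex (the distal tip) to the alpha apex and $c_L = L/2$;
positive values lie toward the alpha (ExE) cap.

## Orientation quantification

Cell surfaces are extracted from label volumes as voxel-face (cuberille)
meshes: closed, consistently outward-oriented, with signed volume exactly
equal to the voxel volume. A cell's boundary normal is the normalized
area-weighted sum of tissue-mesh face normals over its patch — the patch
vector area — which depends only on the patch's boundary ring, so
staircase facets cancel rather than bias the direction. The global tissue
mesh is built from the morphologically closed union mask (sealing thin
membrane gaps so the normals reflect the tissue surface, not inter-cell
crevices), labels are grown into sealed voxels taking the smallest
neighbouring label (a deterministic rule that keeps the pipeline
equivariant under grid rotations), and only the largest connected
component is retained.

Inertia spectra come by default from voxel second moments (solid body,
unit density); the mesh-moment route (divergence-theorem tetrahedra) is
also implemented and the two agree to 1% on ellipsoid fixtures, both
matching the closed-form solid-ellipsoid components
$\propto (b^2{+}c^2,\,a^2{+}c^2,\,a^2{+}b^2)$. The long axis is the
eigenvector of the *smallest* inertia component; the shape anisotropy is
$\eta = (\lambda_3 - \sqrt{\lambda_1\lambda_2})/\lambda_3$, 0 for spheres
and approaching 1 for needles. Polarity signs follow the boundary normal
for boundary cells and the outward centroid direction for interior cells,
with an exactly perpendicular axis keeping its original sign. The
cell-boundary angle is $\arccos|\hat{\mathbf v}\cdot\hat{\mathbf n}|$ in
degrees: 0° means the cell stands perpendicular to the boundary surface,
90° parallel. Neighbouring cells are found by one-voxel 26-connected
dilation overlap (the smallest element catching face, edge and corner
contacts), pairs below 20 µm³ overlap being discarded; the pair overlap is
the larger of the two directed dilation overlaps.

The distal–proximal frame comes from annotations: at least six interface
points (least-squares plane, kept for reporting the cap split height), a
distal-tip point (the axis runs from tip through the tissue centroid), and
two transverse-edge points whose mean fixes the zero-angle rotation plane.

## The nematic field and parameter inference

Coordinates are reoriented so $z$ is the distal–proximal axis and rescaled
to unit tissue volume. At each grid point of a 64×64 half-plane grid, the
elongation axes $\eta\mathbf v$ of the cells occupying the back-rotated
positions in $M = 36$ rotational slices are accumulated into the weighted
Q-tensor (dividing by $M$, so empty slices genuinely dilute the strength —
the formula's stated behaviour); its principal eigenpair gives the
unsigned director (reported with the $V_z \ge 0$ hemisphere convention,
ties broken by $V_x \ge 0$) and strength $\Lambda$. Averaged boundary
curves are obtained by centroid ray-casting on the tissue mask per slice
(crossings estimated midway between the last inside and first outside
sample), with the slice-to-slice spread $d$ retained as the comparison
margin; for the star-shaped domains in scope this is equivalent to
mesh–plane intersection with polar resampling. Cross-embryo averages are
tensor means before eigen-decomposition, never means of directors.

The experimental polarity magnitude is $p_{\mathrm{exp}} = \Lambda /
\Lambda_{\max}$ with $\Lambda_{\max}$ taken over the supplied cohort (all
embryos, all positions). The experimental global order is implemented as
the cylindrical-measure average $\int x\,p_{\mathrm{exp}}\,dx\,dz / \int
x\,dx\,dz$, which is the area-printed formula normalized so a uniform
field of magnitude one scores one and is directly comparable to the
model's $P = \int |\mathbf p|\,dV / V_0$. Comparison points lie in the
intersection of the model and averaged-experimental shapes, more than
0.05 from the axis and more than $d$ from the closest boundary. The fit
minimizes $C = \sum_i [\,|\mathbf p|(\mathbf r_i) -
p_{\mathrm{exp}}(\mathbf r_i)]^2$ over a log-spaced grid (12 values of
$\xi/R_0$ in 0.05–1, 16 of $\lambda/R_0$ in 0.1–20, bracketing the defect
transition), with one warm-started solve per grid point; the solved field
list is cached so noise re-fits reuse it. Directional information is
withheld from the fit and used only for validation: the alignment map
$|\cos\angle(\mathbf p, \mathbf w)|$ and the path projections (three
horizontal paths at $t/4, t/2, 3t/4$ above the distal tip projected on
$\hat x$, three vertical paths at $w/6, w/3, 2w/3$ from the axis projected
on $\hat z$, path coordinates rescaled to $[0,1]$).

## Synthetic embryos

The generator emulates the inputs the pipeline consumes in reality —
corrected membrane-segmentation label volumes with manual axis
annotations — at a desk scale chosen once: characteristic radius
$R_0 = 25$ µm, isotropic 0.8 µm voxels (about $80^3$ voxels), 60 cells by
default (the observed stages span roughly 15–115), per-cell anisotropy
drawn from 0.2–0.8, assuming prolate cells (the elongated epiblast cells
are approximately prolate, and the anisotropy then inverts in closed form
to an aspect ratio). Cells are placed by *anisotropic* dart throwing —
candidate ellipsoids may not penetrate placed ones beyond a tolerated
fraction of their mutual support distance, relaxed progressively if
packing stalls — which is what makes elongated cells pack side by side
the way columnar epithelia do; orientations follow the requested source
(radial, uniform, a composite tangential/radial rule, or a solved field)
with von Mises–Fisher dispersion. Rasterization assigns each in-domain
voxel to the smallest normalized ellipsoidal quadratic form below one and
then grows labels into the interstitial space so the labels tile the
domain: a membrane segmentation of an epithelium is confluent, and the
truncated-ellipsoid-only variant (exposed as `q_max`/`grow` arguments)
leaves crevices that corrupt boundary normals. Field-driven cohorts tie
each cell's anisotropy to the local field magnitude and jitter the cap
parameters between embryos while preserving equator continuity. All
generation is seed-deterministic and each embryo carries a manifest.

What passing the closure tests does and does not show: on these synthetic
embryos the pipeline's measured alignment magnitude correlates with the
generating field and the directors parallel it away from the defect core,
and self-fits recover on-grid parameters exactly; real embryos add
segmentation errors, non-axisymmetric shapes, anisotropy–position
correlations and inter-embryo variability that the generator only
partially emulates (shape jitter, angular noise, annotation jitter).

## Problem sizes and limitations

The shipped tests run the solver at resolutions 0.05–0.1 $R_0$ (roughly
600–2000 nodes), phase diagrams on 6×6 grids, the full 12×16 fit grid
once, and synthetic embryos of 40–80 cells — sizes chosen so the whole
suite completes in minutes while every property is exercised at the same
code paths as larger runs. Known limitations: no dynamics or active
stresses; strictly axisymmetric solves (non-axisymmetric tissue shapes are
out of scope); defect classification near the transition is
resolution-limited as described above; and the cuberille surface area
overestimates smooth areas by the usual staircase factor (volumes,
moments and normals are unaffected, which is why those quantities feed
the pipeline).
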