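---
title: "Curved slices in medical volumes: texturization and isometric flattening"
author: "curvedslices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curved slices in medical volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(curvedslices)
```

## The problem

CT and MRI studies arrive as stacks of planar slices, but the anatomy a
clinician wants to follow -- the muscle sheath around a humerus head, the
dental arch of a jaw, the centerline of an aortic aneurysm -- is curved.
This package places *curved slices* (parametric surfaces fitted to the
region of interest) inside a 3D volume, paints them from the surrounding
data ("texturization"), and, when the surface is developable, unfolds it
into the plane with zero metric distortion, so lengths and areas measured
on the flat image equal those on the curved slice.

## Volume geometry

Each DICOM file carries `ImagePositionPatient` (the 3D position of pixel
(0, 0)), `ImageOrientationPatient` (unit direction vectors of the pixel
rows and columns) and `PixelSpacing`. Pixel $(i, j)$ (row, column; 0-based)
of a slice therefore sits at

$$p(i, j) = o + i\,s_r\,\mathbf{r} + j\,s_c\,\mathbf{c},$$

a point sample in millimetres. We treat pixels as point samples, not area
cells. The slice normal is $\mathbf{r} \times \mathbf{c}$ and the series is
ordered by the projection of the origins onto it (file-name ties broken
lexicographically, for determinism). A stack is *regular* when all slices
share pose and in-plane geometry; slices need **not** be equidistant --
the interpolation uses each slab's actual extent. Non-parallel stacks
(e.g. stomach studies) are kept as scattered point sets.

Gray levels are stored exactly as read; rescale slope/intercept and
window/level are display concerns, applied only at PNG export (default
window: the volume's 1st--99th gray percentiles).

## Texturization

Two painters assign a gray level to each sample of a surface
$S : [0,1]^2 \to \mathbb{R}^3$:

* **Trilinear interpolation** (regular stacks only). The query's unique
  lattice cell is found by binary search on the per-axis coordinate arrays
  (this is what makes non-uniform slice spacing work), local coordinates
  $\alpha, \beta, \gamma \in [0,1]$ are computed from the cell's actual
  extents, and the eight corner grays are blended with weights
  $(1-\alpha)(1-\beta)(1-\gamma), \ldots, \alpha\beta\gamma$. The weights
  sum to one, so the result is bounded by the corner grays and continuous
  across cell faces.
* **Nearest neighbor**. The volume's bounding box is tiled into
  $m_x m_y m_z$ congruent sub-boxes (half-open intervals; the upper
  boundary closes the last box), every data point lands in exactly one
  bucket, and a query receives the gray of the Euclidean-nearest data
  point *within its own sub-box only*. Distance ties break to the lowest
  insertion index. This needs no grid structure at all, so it serves
  arbitrarily posed slices. When the query's sub-box is empty the sample
  is *uninformed*: it carries the sentinel gray $-1$ plus a mask bit and
  renders as pure blue. As the division count grows, empty sub-boxes --
  and hence uninformed samples -- become more frequent; with sixteen
  sparse slices the jump from $17^3 = 4913$ to $20^3 = 8000$ sub-boxes is
  clearly visible.

Searching only the query's own sub-box is deliberate: it is the plain
statement of the rule. An optional extended mode that also searches the 26
adjacent sub-boxes is available (`extended = TRUE`) and is off by default.
Surface samples outside the volume are marked uninformed rather than
clamped, to avoid fabricating data.

```{r texturize-example, eval = FALSE}
fld <- brightShellField(center = c(32, 32, 30), a = 18, b = 18)
vol <- generatePhantom(phantomSpec(fld, nSlices = 16L,
                                   matrixDim = c(64L, 64L),
                                   spacing = c(1, 1, 4)))
surf <- ellipsoidPatch(c(32, 32, 30), c(0, 0, 1), 18, 18)
tex <- texturizeSurface(surf, vol, "nearest", resolution = c(64L, 64L),
                        divisions = 17L)
uninformedCount(tex)
```

## Fitted surfaces

* **Ellipsoid of revolution** (`fitEllipsoidRevolution`):
  Levenberg--Marquardt least squares on the algebraic residual
  $(h/a)^2 + (\rho/b)^2 - 1$ in the axis-aligned frame, initialized from
  the cloud centroid and each of the three principal directions (the
  best-converged start wins; for a sphere the axis is arbitrary and any
  start is fine). The patch covers the half on the side holding most of
  the cloud. Radial offsets (`offsetRevolution`) change every latitude
  circle's radius about the axis by a constant while keeping the axial
  coordinate -- a radial, not surface-normal, offset -- producing the
  inward/outward inspection shells. Offsets accumulate in a slot, so
  $+\delta$ then $-\delta$ is an exact inverse; negative totals clip the
  latitude domain to circles of positive radius instead of folding
  through the axis.
* **Bezier centerline** (`fitBezierLsq`): linear least squares in the
  Bernstein basis by QR (rank-tested at $10^{-12}$ because the basis is
  ill-conditioned long before it is truly deficient; genuinely deficient
  systems are ridge-regularized with a warning). Raw point clouds get
  chord-length parameters; callers with known sample parameters may pass
  them explicitly, and exact polynomial recovery holds in that case. No
  parameter-correction iteration is performed -- a recorded extension
  point.

## Developable surfaces

A ruled surface $x(t, u) = c(t) + u\,r(t)$ is developable exactly when
$\det[\dot c, r, \dot r] = 0$. `developabilityDefect` reports
$|\det[\dot c, r, \dot r]| / (\lVert\dot c\rVert\,\lVert\dot r\rVert)$
(zero for $\dot r = 0$), and every construction below keeps it at the
$10^{-6}$ level or lower; `unfoldSurface` refuses inputs above $10^{-5}$.

Three generators are provided:

* **cylinder**: $r(t) = d$ constant.
* **envelope**: the envelope of planes through $c(t)$ with normal
  $N(t) = \widehat{\dot c \times d}$; the ruling is the characteristic
  direction $\widehat{N \times \dot N}$. Because rulings are lines, the
  unit field carries a sign ambiguity that flips where $\dot N$ crosses
  zero; a construction-time orientation pass over a dense grid makes the
  field continuous. Two orthogonal reference directions give a pair of
  surfaces intersecting transversally along the same curve.
* **rectifying**: rulings along the Darboux direction
  $\tau T + \kappa B$. The directrix is then a geodesic of the surface
  and flattens to a straight line. Curvature must stay positive; at
  inflections the construction fails fast rather than interpolating
  frames.

These three constructions were chosen because their developability is
checkable by a single closed-form condition and together they cover the
observable uses -- cylinder-like panoramic slices, transversal pairs along
a centerline, and pregeodesic flattening. Exact developable-Bezier control
nets and cone splines are out of scope.

## Isometric flattening

Geodesic curvature is invariant under isometric unfolding, so the planar
image $\bar\alpha$ of the directrix $\alpha$ satisfies
$\bar\kappa = \kappa_g$ and can be reconstructed from

$$\phi(t) = \int v(t)\,\kappa_g(t)\,dt, \qquad
  \bar\alpha(t) = \int v(t)\,[\cos\phi(t), \sin\phi(t)]\,dt,$$

with $v = \lVert\dot\alpha\rVert$. We fix the congruence freedom by
anchoring $\phi = 0$, $\bar\alpha = (0,0)$ at the first sample (the
anchor index is a parameter; changing it yields a congruent sheet, which
the tests verify by Procrustes alignment). Rulings are drawn in the plane
at the same angle to $\bar\alpha$ as in 3D -- concretely
$\bar r = \langle r, T\rangle\,\bar e_1 + \langle r, n \times T\rangle\,
\bar e_2$, which also settles the side of the curve -- with their 3D
lengths preserved. The texture and informed-mask ride along per sample.

Numerical choices: both integrals use the composite trapezoid rule on the
caller's $t$ grid (order 2; the grid density is the accuracy knob).
Geodesic curvature of the directrix is
$\langle\ddot\alpha, n \times T\rangle / v^2$ with $n = \widehat{\dot c
\times r}$; for general curves on general surfaces the foot point is
found by a coarse grid search plus bounded quasi-Newton refinement, and a
curve more than $10^{-6}$ mm off the surface is an error. Derivatives of
closure-backed quantities use 4th-order finite differences (5-point
one-sided stencils at the ends -- lower-order end stencils were the
dominant error source in the developability test). $\phi$ is obtained by
integration, so no $2\pi$ unwrapping issue arises.

`flatteningDistortion` audits a flattening by comparing the first
fundamental form $E, F, G$ (central differences on the shared grid) and
the triangulated areas of the 3D and planar grids. Exact developables
audit at the discretization level (about $10^{-4}$ relative at a
$200 \times 51$ grid, order 2 in the directrix grid); a deliberately
twisted ruled surface fails by two orders of magnitude, which the tests
use as a negative control.

## The phantom generator

Synthetic volumes make every stage testable without clinical data. A
`PhantomSpec` fixes an analytic gray field, slice count, matrix, spacings,
pose mode, and a single integer seed from which all randomness (slice-gap
jitter, fan angles) flows; equal specs give byte-identical DICOM series.
Fields: exact trilinear ramps (the interpolation oracle), bright shells
with angular defect patches (tear-like gaps around a fitted ellipsoid),
bright tubes with a Gaussian-bulge radius (aneurysm-like), and vertical
cylinders along a parabola $y = ax^2$ (the dental arch, which the
maxillofacial literature describes as parabolic). Default gray range is
0--4095 (12-bit CT-like) with background 100 and bright structures 3000.

What the phantoms do *not* emulate: scanner noise spectra, partial-volume
averaging, bias fields, or anatomical texture. Passing tests therefore
demonstrate geometric and numerical correctness of the pipeline, not
robustness to imaging physics.

The DICOM writer emits minimal single-frame Explicit VR Little Endian
files (geometry fields, Rows/Columns, 16-bit pixel data) plus a JSON
sidecar recording the spec; the reader handles explicit and implicit VR
little endian, and the test suite cross-checks written files against an
independent Python DICOM reader.

## Problem sizes and defaults

The test suite and the acceptance script use: $64^3$ ramp phantoms for
interpolation exactness (1000 random probes), 5000 scattered points with
500 queries for the nearest-neighbor oracle, sixteen $64 \times 64$
slices at 4 mm gaps for the uninformed-growth comparison ($17^3$ vs
$20^3$ sub-boxes), 2000-sample developments for the circle and cone
closed forms, and $200 \times 51$ grids over ten random curves for the
isometry audit. CLI defaults: $256 \times 256$ samples for texturization,
$256 \times 64$ for flattening.

## Known limitations

* Nearest-neighbor search is exact but plain R; very large volumes are
  better served by coarser division counts or the trilinear path.
* Developments that wrap beyond $2\pi$ may self-overlap in the plane; no
  overlap resolution is attempted.
* The DICOM subset is deliberately small: single-frame, uncompressed,
  little endian, no sequences.
* The envelope construction degenerates when the reference direction is
  (near-)parallel to the tangent or when $\dot N$ vanishes identically
  (planar curve with perpendicular reference -- use the cylinder there).
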