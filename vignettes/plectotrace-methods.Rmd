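---
title: "Tracing and quantifying supercoiled plasmid topology: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing and quantifying supercoiled plasmid topology: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plectotrace)
```

## Scope and model

Negatively supercoiled circular DNA partitions its linking-number deficit
ΔLk between twist and writhe, ΔLk = ΔTw + Wr, and at physiological
superhelical densities (σ = ΔLk/Lk₀ ≈ −0.06 to −0.08) adopts plectonemic
conformations: two duplex segments interwound about a superhelical axis,
capped by high-curvature apical loops, sometimes branching into multi-armed
stars. Per-particle cryo-electron tomography can resolve individual ~2 kbp
plasmids well enough to trace the full duplex centerline in 3D, after which
the molecule's topology is directly measurable.

`plectotrace` implements that measurement chain:

1. **Tracing** — recover a closed centerline (a `closed_curve`, ordered 3D
   points in nm) from a single-particle density volume;
2. **Topology** — writhe, curvature and apices, radius of gyration,
   superhelical-axis spacing, branch decomposition, per-branch writhe
   density, and ΔLk/σ/ΔTw bookkeeping;
3. **Localization** — relate bound protein particles (RNA polymerase,
   dCas9, …) to the traced curve: bound/unbound, apical vs off-apex,
   fiducial-anchored base-pair coordinates, pairwise angular separations;
4. **Synthetic data** — exact ground-truth plectonemes, rendered volumes
   and planted particles, so every stage is testable without experimental
   data.

All geometry is in nanometres internally; MRC headers (Ångström) are
converted at the file boundary.

## Topological estimators

**Writhe.** The Gauss double integral over the closed curve is evaluated
with the exact per-segment-pair solid-angle expression (the closed-form of
Klenin & Langowski's method 1a) over all non-adjacent segment pairs.
Right-handed crossings contribute negatively, so negatively supercoiled
plasmids have Wr < 0. The exact pair formula, rather than midpoint
quadrature, is what makes a 2 nm discretization sufficient: on the
synthetic battery the 2 nm result is within 0.05 of the same integral at
0.25 nm (the package's reference discretization), and the unit tests also
cross-check it against an independent midpoint-quadrature implementation.
Segment pairs closer than 0.1 nm trigger a warning naming the offending
indices, since the integrand degenerates at contact.

**Curvature.** At each point the circumscribed-circle formula
κ = 1/R = 4S/(fgh) is applied to the triangle formed with the two cyclic
neighbours (S its area; f, g, h its side lengths). Collinear triples give
κ = 0 exactly. On a 2 nm-spaced circle of radius 10 nm this reproduces
κ = 0.100 nm⁻¹ to well under 1%.

**Apices.** The curvature profile is smoothed along arc length (Gaussian
window, default 10 nm), and strict local maxima are kept when their
prominence is at least 0.05 nm⁻¹ and they are at least 30 nm apart along
the curve. These thresholds are this package's operating point — chosen so
that apical loops (κ ≈ 0.2–0.3 nm⁻¹ at the ~5 nm cap radii typical of
these plasmids) stand far above them, while gentle junction bends
(κ ≲ 0.04 nm⁻¹) stay below — and are exposed in the configuration.

**Radius of gyration.** The gyration tensor of the curve points about
their centroid is diagonalized; its eigenvalues are reported sorted
descending and Rg = √(λ₁+λ₂+λ₃), the root-mean-square distance from the
centroid. (A literal sum of squared eigenvalues would be dimensionally a
fourth power of length; the square root of the eigenvalue sum is the
standard definition and reproduces the tens-of-nm scale expected for these
particles.)

**Superhelical axis and spacing.** The curve is cut at its apices into
strand groups; each point is paired with its nearest point of any other
group, excluding partners closer than 20 nm along the curve so that the
pairing cannot simply step across an apex cut. Pair midpoints trace the
axis, pair distances give the local inter-strand spacing, and the first
apex anchors the zero of the axis arc coordinate. On ideal interwound
geometry with 8 nm strand spacing the recovered mid-arm spacing is
8 ± 0.5 nm and rises toward the cap diameter at the apices.

**Branches.** Axis points are clustered by single linkage; junction
regions are detected where at least three distinct strand passes converge
within the junction radius (15 nm), and two-armed junctions — which leave
the axis graph degree-2 — are caught by a corner test (direction change
above 60° integrated over ±30 nm of axis, outside the distal cap zones).
Each curve point is assigned to the branch of its nearest non-junction
axis point. Branch length is the polyline length of the branch's reference
strand pass.

**Writhe density.** Each branch's points are treated as a smaller closed
curve (straight chord closure). Branches whose axis exceeds 100 nm are cut
into consecutive equal units along the axis (n = ⌊L/100⌋, so units are
100–199 nm; shorter branches form single units), and each unit is scored
as writhe per unit axis length. Chord closure introduces a bounded
artifact; on the synthetic battery the summed unit writhes reconstruct the
total Wr within |0.1·Wr| + 0.3.

**Linking-number arithmetic.** σ = ΔLk/Lk₀ with Lk₀ = round(bp/10.5), and
ΔTw = ΔLk − Wr; both derived quantities are always recomputed from their
inputs. For the ~2 kbp construct: Lk₀(1950) = 186, σ(−15) ≈ −0.08,
σ(−8) ≈ −0.04.

## The tracing pipeline

`trace_plasmid()` composes four deterministic stages (no randomness
anywhere in tracing):

**Spine.** The volume is smoothed with a strong Gaussian kernel (default
sd 8 nm, of the order of the plectoneme width, so the two strands merge
into one tube), binarized at the 0.90 quantile of its positive voxel
densities, reduced to its largest connected component, and thinned to a
one-voxel-wide skeleton with a topology-preserving (26,6) thinning (direct
simple-point test: one 26-connected object component in the neighbourhood
and one 6-connected background component touching a face neighbour;
deletion in six directional subiterations). Spurs shorter than 15 nm are
pruned; the skeleton is returned as a graph whose simple paths are the
spine lines, with junction nodes retained.

**Sampling cylinder.** Stepping 5 nm along each spine path, voxels above
threshold inside a 60 nm × 15 nm cylinder (axis = local spine tangent) are
split into two regions by the sign of the first principal component of
their in-plane coordinates — a planar cut through the cylinder axis — and
each region's density-weighted centroid is recorded. Three robustness
rules matter in practice and are part of the method: (i) voxel weights are
tapered along the cylinder axis (Gaussian, sd = height/4), because the
strands rotate about the spine and distant slices smear each strand into
an arc that defeats the two-region split; (ii) the density threshold is
the 0.90 quantile of positive voxels *floored at 3.5 robust background
standard deviations* (median absolute deviation), because on noisy maps
the plain quantile lands inside the noise tail and the centroids become
noise-dominated; (iii) records need at least 20 supporting voxels, and
each region at least 10 — a handful of voxels above threshold is residual
noise, not a strand. Degenerate splits (single strand in the cylinder,
e.g. apical caps) are flagged and recorded as single centroids, never
dropped silently. Free (degree ≤ 1) spine ends are extrapolated 20 nm so
the caps beyond the skeleton are still sampled.

**Linking.** For structured center samples the linker exploits the step
structure: at each step the two centroids are assigned to two strand
*rails* by continuity (distance to the current rail ends, swap allowed),
gross outliers are rejected (midpoint residual > 4.5 nm — more than strand
curvature can produce), rails are joined across each apical cap through
the degenerate records (ordered by angle over the cap chord), and
junction-side rail ends — whose last ~20 nm are discarded as mixed-density
— are paired by following the density ridge through the junction
(cone-weighted centroid walk with direction momentum); mutually confirmed
walks fix the transits and contribute their points, and any remaining ends
are paired by the minimal-cost perfect matching (transit length plus
tangent misalignment) that closes the whole assembly into a single cycle.
A bare point matrix — shuffled centers, or an edited center list supplied
as an intervention file, the scriptable analogue of manual correction — is
linked greedily instead: unvisited candidates within 25 nm, smallest
turning angle first, turns above 130° only at dead ends, limited
backtracking. Unplaceable centers are reported in an `unresolved`
attribute, never guessed; if no closed tour exists the error names the
break.

**Refinement.** The closed path is smoothed by local quadratic regression
along arc length (window 3× the target spacing by default; the pipeline
uses 10 nm ≈ two center steps) and resampled at uniform 2 nm spacing with
periodic cubic splines. A local quadratic, unlike a plain moving average,
passes smooth arcs essentially unchanged — no inward curvature bias — which
is what makes refinement idempotent (< 0.2 nm RMS on re-application) and
keeps circles circular to within 5% curvature uniformity.

## The synthetic generator

Ground truth is built analytically rather than by physics simulation:
exact geometry, exact topology, millisecond cost.

* An unbranched plectoneme is two antiparallel helical strands (radius =
  strand_spacing/2) about a straight axis, capped by tangent-continuous
  cubic Hermite loops of nominal radius `apex_radius`. One *interwound
  turn* means one inter-strand crossing (half a strand revolution), so the
  writhe magnitude tracks the turn count: 660 nm, −6 turns, 8 nm spacing
  gives Wr ≈ −5.9. Negative turns wind right-handed and give negative
  writhe.
* Branched stars place 2–5 such arms around a junction (two arms at 90°,
  more spread evenly; arms staggered ±4 nm in z), joined by Hermite
  connectors. Junction geometry is deliberately blunt (bend radii
  ≥ ~30 nm, κ ≤ 0.04 nm⁻¹, strand phases held near π/2 at the junction):
  a junction that read as an apex would be an artifact of the generator,
  not a property of the estimators under test.
* The reference writhe of every generated curve is the Gauss integral on a
  0.25 nm resampling; the returned curve is 2 nm-spaced by default. All
  generators are deterministic per seed, and self-avoidance at the duplex
  diameter is asserted after construction — violations raise, never return.
* `render_density()` sums one unit-peak isotropic Gaussian kernel
  (sd = 2 nm, emulating a 2 nm low-pass map) per curve point on a voxel
  grid (default 1.5 nm voxels) and adds seeded i.i.d. Gaussian noise; the
  ridge peak is ≈ 2.5, so noise sd 0.5 gives peak SNR 5. The noise model
  is additive and isotropic only: missing-wedge anisotropy, CTF effects
  and detector statistics of real tomograms are *not* emulated, so passing
  recovery tests demonstrate correctness of the geometry chain, not
  robustness to every artifact of experimental maps.
* `place_particles()` maps base-pair positions to arc positions
  (proportional scaling, ~0.34 nm/bp), displaces centers outward along the
  local normal, and optionally renders spherical Gaussian blobs.

The standard recovery battery (`recovery_battery()`) is ten particles at
the ~2 kbp scale — four unbranched (−5 to −8 turns), two two-armed and
four three-armed stars — rendered at 1.5 nm voxels and SNR 5. Geometry
seeds are fixed (they are the study conditions); the rendering noise seed
is derived from the caller's seed. On this battery the pipeline typically
recovers writhe to better than 0.1, contour length to ~2%, the apex count
exactly in 8–10 of 10 cases, and branch assignment above 99%.

## Localization conventions

Binding uses the strict sub-1 nm center-to-vertex criterion of the
published protocol as its default; that presumes 2 nm model spacing and
particle centers refined onto the DNA, so synthetic blob-rendered
particles are tested with a threshold matched to their placement offset.
A bound particle is *apical* when its nearest curve point is within 20 nm
arc of an apex (inclusive); the window is a package decision — about one
protein diameter plus a cap — since published apical/off-apex ratios do
not state their cutoff, and it is flagged as such in the documentation.
Base-pair coordinates rescale arc length to `total_bp` (default 1950) with
the fiducial's nearest point at `fiducial_bp` (default 1090, the dCas9
site); the traversal direction must be stated explicitly — it is never
guessed — because a centerline trace carries no intrinsic sequence
orientation. Pairwise angular separations are 2π·min(d, N−d)/N for bp
distance d, giving values in (0, π]; 2.7 rad on the 2.8 kb dual-promoter
construct corresponds to ~1.2 kbp.

## Numerical choices and degenerate inputs

* Writhe: asin arguments clamped to [−1, 1]; coplanar segment pairs
  contribute zero; open curves and fewer than 4 points are errors.
* Curvature: duplicate points in a triple are an error (the circumscribed
  circle is undefined); collinearity is exact zero.
* Apex detection: an empty apex set is valid (a circle has none); fewer
  than two apices means no interwound region and the axis constructor
  says so.
* Thinning and linking are fully deterministic: fixed voxel orderings,
  index-based tie-breaks, no random initialization.
* MRC I/O is little-endian mode 0/1/2; anisotropic headers are averaged
  with a warning; malformed headers name the offending field.

## Known limitations

* Junction transits recovered by ridge walks can carry residual curvature;
  in 1–2 of 10 battery cases under unfavourable noise this yields one
  extra (or one merged) apex call. The two-armed V is intrinsically
  ambiguous at its junction: ~5% of points near the corner have no
  uniquely correct branch owner.
* Apical cap tips can be undershot by up to ~10 nm when the last sampled
  pair sits short of the tip, which slightly biases contour length
  downward; the effect is within the battery's 2% median contour error.
* Twist is only ever obtained by bookkeeping (ΔTw = ΔLk − Wr); a
  centerline carries no ribbon frame, so no geometric twist is computed.
* One particle per volume; no knot detection; no missing-wedge or CNN
  segmentation steps (those belong upstream of this package).

## Problem sizes

The test suite and the acceptance script run the ten-particle battery at
1.5 nm voxels (volumes of ~10⁵–10⁶ voxels), the writhe oracle at 0.25 nm
discretization (~2,600 points, ~3.5 million segment pairs per curve), and
complete in well under a minute on a single core — sizes chosen to make
the validation exhaustive yet quick to reproduce.
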