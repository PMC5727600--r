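---
title: "Physical-disector stereology: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physical-disector stereology: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(disectr)
```

## The estimation model

A particle population inside a region of interest is sampled in two nested
stages. First, every k-th section of a serial series is taken (section
sampling fraction ssf = 1/k), each sampled section forming a *disector pair*
with its cutting-order neighbour mounted on the same slide. Second, an
unbiased counting frame of area a(frame) is placed at every node of a
systematic X–Y grid (area sampling fraction asf = a(frame)/(X·Y step)),
with the grid offset and the section start drawn uniformly at random — the
defining property of systematic uniform random sampling. A counting event
occurs when a profile sampled by a frame appears in one section of the pair
but not in the other; both directions are counted, so every particle gets
two chances. The fractionator then scales the counted events back through
the known fractions:

$$N = \frac{1}{ssf}\cdot\frac{1}{asf}\cdot\frac{\Sigma Q^-}{2},
\qquad
V = \Sigma P \cdot X_{step} \cdot Y_{step} \cdot t \cdot \frac{1}{ssf}.$$

Unbiasedness rests on two geometric facts that the package tests directly
rather than assumes. The counting frame's exclusion line (left edge extended
upward, bottom edge, right edge extended downward) makes an exhaustive
tiling of frames count every profile exactly once, so a sparser grid samples
each profile with probability exactly asf. And every particle has exactly
one "top" slab — the section containing its highest point — so bidirectional
disector counting over adjacent pairs counts each particle's top and bottom
each with probability ssf.

## Tunable parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `ssf_period` | 50 | sections | every k-th section sampled |
| `frame_area` | 60,000 | µm² | unbiased counting frame area |
| `step_x`, `step_y` | 387.29 | µm | frame grid spacing |
| `section_thickness` | 5 | µm | slab thickness t (microtome setting or caliper-derived) |
| `disector_separation` | = t | µm | distance h between pair members |
| `smoothness_constant` | 240 | — | denominator of Var_SURS for this design class |
| `r_match` | mean profile radius | µm | centroid match tolerance without particle ids |
| alignment `threshold` | 0.5 | NCC | below it the pair is flagged for manual override |

The defaults are the constants of a rat substantia nigra study design:
every 50th 5-µm section gives 10–15 usable pairs over the region's
rostro-caudal extent, and the 60,000 µm² frame on a 387.29 µm grid
(asf ≈ 0.40, 1/asf ≈ 2.50) yields roughly 150–200 counting events per
hemisphere — enough, per the 50%-of-variance rule below, for the sampling
error to be dominated by biological variation.

## Error prediction

Because SURS samples are not independent, the CE of a number estimate is
predicted from the ordered per-pair counts with the three product sums
A = Σq²ᵢ, B = Σqᵢqᵢ₊₁, C = Σqᵢqᵢ₊₂:

$$\mathrm{Var}_{SURS} = \frac{3(A - noise) - 4B + C}{240},\qquad
CE = \frac{\sqrt{noise + \mathrm{Var}_{SURS}}}{\Sigma Q^-},$$

with noise = ΣQ⁻ for number estimates. The 240 constant encodes the
smoothness class of the measurement function for this design; it is stored
in the design object, not hard-coded, since other designs use other
constants. Volume estimates require a different noise term which this
package deliberately does not implement; volume results therefore carry no
CE. For a group, the mean CE is the root mean square of the individual CEs,
and the observed CV decomposes as CV²_obs = CV²_biol + CE̅²; the design is
deemed acceptable when CE̅²/CV²_obs < 0.5. Where typography in the source
material was ambiguous, the root-mean-square reading of the group CE and
the square-root form of the CE were adopted — they are the forms consistent
with the worked numbers (CE = 0.08 from the example series) and with the
stereological literature the formulas descend from.

Numerical choices: a short or flat count series can make the raw Var_SURS
negative; it is clamped to zero with a warning and both values are kept,
because a variance prediction cannot be negative and the CE must stay real.
Reported values follow the display conventions of published tables — N
rounded to the nearest integer half away from zero, V and CE at two
decimals — while all downstream arithmetic uses full precision. One
deliberate exception: reproducing a published table exactly requires the
2-decimal 1/asf it was computed with (2.50 rather than 2.49989), so
`fractionator_estimate()` accepts an explicit `inv_asf` override; pipelines
default to the unrounded value.

## The counting frame convention

The exclusion edges are the left and bottom edges, the inclusion edges the
top and right, with the infinite extensions running up from the top-left
corner and down from the bottom-right. Source figures of such frames are
rarely reproduced sharply enough to fix the orientation, so this is
documented as a convention: any consistent orientation yields the same
tiling property, which the tests verify by brute force (1,000 random discs
against an exhaustive tiling, each counted exactly once). "Touching" an
edge means non-empty intersection of the closed profile with the edge
segment or ray; in raster mode a label mask object is reduced to its
centroid and equivalent-area circle first. Vector-mode decisions are
implemented for circular profiles; irregular shapes enter via label masks.

## Alignment

Adjacent-section images are registered with a rigid transform maximising
normalized cross-correlation, searched coarse-to-fine (downsample factors
4, 2, 1). The coarsest level scans translation only — sub-degree rotations
barely move coarse pixels — the middle level sweeps the full rotation range
at 0.5°, and the final level refines to 0.25° and single pixels. Ties in
the similarity score keep the smallest motion, so an already-registered
pair returns the identity. When the best similarity falls below the
confidence threshold (default 0.5) the pair is flagged and
`apply_manual_override()` records an operator-supplied transform in an
audit log instead of silently proceeding — mirroring the manual-fallback
contract of commercial autodisector systems, whose internal search is
unpublished. Validation: over 100 synthetic pairs with shifts up to ±50 px
and rotations up to ±5°, at least 95% are recovered within 2 px and 1°.

## The phantom simulator

`generate_phantom()` places n spheres uniformly in a box or ellipsoid ROI
with a minimum centre separation (rejection sampling on a spatial hash
grid), radii uniform in 5–10 µm — the scale of nigral somata; 2 µm
separation keeps rendered profiles from merging in raster mode.
`virtual_sectioning()` cuts half-open slabs [i·t, (i+1)·t) — half-open so a
boundary-straddling coordinate belongs to exactly one slab — and gives each
sphere a disc profile of the radius at the slab midplane (clamped to a small
ε when the midplane falls just outside the sphere). The midplane radius
rather than the slab-union radius keeps the geometry simple; profile size
does not enter number estimation, so the simplification cannot bias N.
`simulate_study()` then runs the identical code path used for real counts:
SURS section selection, per-pair grids, bidirectional `disector_count()`
with particle-id matching, and one Cavalieri test point per grid node.

What the phantom emulates: a serially sectioned particle population with
known true N and V, the pairing of adjacent sections, and realistic
counting yields (the default study design on a 10,000-particle phantom
gives ΣQ⁻ ≈ 160 in ~12 pairs). What it does not emulate: staining
variability, section deformation, lost caps or split profiles, and
profile-matching ambiguity (ids are known). Passing phantom tests therefore
demonstrates the correctness of the sampling mathematics and its
implementation, not robustness to histological artefacts.

Simulated lesion cohorts (`generate_lesion_cohort()`) draw contralateral
baselines lognormally around 10,000 neurons (between-animal CV 0.25,
matching a contralateral mean of ~10,300 with SEM ~530 at n = 26), apply a
mean-one lognormal lesion factor around the designed fractional loss
(default 0.55, the partial-lesion scale; 0.85 for full lesions), and link
amphetamine rotations linearly to fractional loss (500 net turns per unit
loss, SD 100) with a four-fold weaker apomorphine link — reproducing the
qualitative behavioural contrast that only the indirect agonist tracks
partial lesions. These values are generator conditions, chosen once to
match the study scale, not fitted quantities.

## Problem sizes used in validation

The test suite validates unbiasedness with 200 seeded replicates of the
default design on one 10,000-particle phantom (mean N̂ and V̂ within 2 Monte
Carlo SE of truth), the census limit (ssf = asf = 1) exactly for N and
within 1% for V, the counting-frame tiling on 1,000 discs exactly, and
alignment recovery on 100 pairs. Smaller versions of the same properties
run in the per-module tests. These sizes give Monte Carlo standard errors
a factor ~5 below the effects being tested while keeping the suite quick to
run.

## Known limitations

* No guard zones or optical (z-stack) disector: the implementation targets
  thin physical sections, where guard zones are unnecessary.
* Volume CEs are not predicted (different noise model, out of scope);
  shrinkage enters only through the caliper-derived thickness, so absolute
  volumes on processed tissue should be compared within-study only.
* Vector-mode counting assumes convex (circular) profiles; concave objects
  should go through label masks.
* Rigid alignment only; deformable registration of damaged sections is the
  manual operator's job, via the override path.
* The permutation p-value of `rank_correlation()` is exact only for n ≤ 8;
  beyond that it is Monte Carlo with a seeded generator.
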