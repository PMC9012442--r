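---
title: "Phantom-based CT kinematics of interspinous ligament desmotomy"
author: "spinekin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phantom-based CT kinematics of interspinous ligament desmotomy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Interspinous ligament desmotomy (ISLD) is a surgical treatment for
"kissing spines" (overriding dorsal spinous processes, ORDSP) in horses.
Its effect on spinal mobility can be quantified *in silico*: a thoracolumbar
segment (T11--L1, eight interspinous spaces) is CT-scanned in resting,
flexion and extension loading phases, before and after desmotomy of all
eight spaces; each vertebra is segmented from the bone window
(+700 to +3000 HU), the phases are superimposed rigidly on the T11 anchor
vertebra, and mobility is read off as

* **local** measures: the distance between the craniodorsal landmark points
  of adjacent dorsal spinous processes (inter-DSP distance), one repeatable
  point per vertebra; the per-space dorsoventral range of motion
  (ROM, |flexion − extension| distance); the total T11--L1 length; and
* **global** measures: the excursion of L1 (the bone farthest from the
  anchor) between flexion and extension, decomposed into dorsoventral,
  craniocaudal and mediolateral translation components and rotation angles,
  plus the Hausdorff distance between the flexion and extension L1 surfaces
  as the "maximal excursion" reading.

Real cadaveric studies cannot be re-measured without their raw scans, so
`spinekin` rebuilds the entire measurement chain on *synthetic phantoms with
known kinematics*: every operation - voxelization, segmentation,
registration, measurement, statistics - can therefore be validated against
ground truth. The anatomical frame is +x cranial, +y left (mediolateral),
+z dorsal throughout; distances are mm, angles degrees, intensities
Hounsfield units.

## The spine phantom

`spine_template()` describes a stylized nine-vertebra segment. Each vertebra
is one watertight solid: a vertebral-body block (18 x 40 x 45 mm by default)
carrying a 120 mm dorsal blade. The blade leans cranially
(`dsp_cranial_taper` = 0.36, i.e. the tip is 43 mm cranial of its base) and
ends in a small flat shelf whose cranial edge slants both mediolaterally and
dorsoventrally. That shape is deliberate: the craniodorsal landmark rule
("the most cranial vertex in the dorsal 40% of the mesh") must select the
same physical point on an analytic mesh and on its voxelized, segmented,
smoothed counterpart, including under the tilts the loading phases induce.
The slanted shelf makes the apex the unique maximizer with a strict margin
in both the cranial and dorsal directions, and the flat landing keeps the
apex voxel populated at any grid alignment. A needle-sharp or flat-topped
blade fails one or the other (we measured landmark errors up to several
voxel diagonals before settling on this shape).

Consecutive craniodorsal landmarks sit `resting_gap` = 39.9 mm apart, the
resting inter-DSP distance of mature horses; the straight-line T11--L1
distance is `target_total_length` = 310 mm. Because 8 x 39.9 mm exceeds
310 mm, the landmark chain is bent onto a circular arc (center dorsal of the
landmarks, so the vertebral bodies spread rather than converge). Vertebra
*orientations* stay upright along the arc: the arc fixes positions only.
Following the arc tangents would tilt the end vertebrae by +/-24 degrees,
which is outside the stability envelope of the craniodorsal-vertex rule on
voxelized surfaces; upright resting orientations keep all phase tilts below
about 15 degrees.

## Articulation

`articulate()` applies a forward-kinematic chain: vertebra *i* carries the
composed product of the joint rotations at spaces 1..*i*−1, each about the
mediolateral (y) axis through that space's pivot, evaluated in the resting
frame; T11 stays fixed and the resting phase returns identity transforms.
Flexion closes the interspinous gaps (the loading-rig convention in which
the dorsal strap compresses the DSPs); extension opens them. We note the
published per-phase distance tables are internally inconsistent with that
convention (their flexion means exceed their extension means); the
generator follows the closing-flexion convention and exposes
`swap_phase_labels` in `study_config()` to reproduce the opposite labeling.
The per-space ROM, |flexion − extension|, is invariant to the choice.

**Pivot placement.** The pivot sits `pivot_offset` = 450 mm ventral of the
DSP tips - a *virtual* center of rotation well below the vertebral canal -
rather than on the vertebral-body center line (~140 mm). The reason is
quantitative consistency: closing a gap by the observed ~9 mm about a
140 mm lever needs ~3.6 degrees per joint, i.e. ~29 degrees of cumulative
L1 rotation before desmotomy, far above the 12-22 degrees actually observed
between flexion and extension in such segments; no single near-anatomical
pivot reproduces both numbers under rigid per-joint rotation. The deep
pivot reproduces the per-space ROM calibration *and* L1 rotations of the
observed order (18.8 degrees pre, 24.9 post in the default phantom), at the
cost of a more translation-like (shear) closing motion. The L1 translation
excursions that result (tens of mm, up to ~100 mm craniocaudally) remain
larger than the published 23-48 mm; the phantom reproduces the *sign
structure and per-space calibration* of the intervention, not every global
magnitude.

**Calibration.** The default joint amplitudes are fixed once by
root-finding on the default template (`scripts/calibrate_defaults.R`):
flexion and extension amplitudes (~1.18 degrees each) such that the mean
gap closes/opens by 8.95 mm, giving the pre-desmotomy mean per-space ROM of
17.9 mm; and the desmotomy flexion multiplier (1.6397) such that the
post-desmotomy ROM is 23.5 mm. Desmotomy multiplies the flexion amplitude
only - the procedure releases tension and so affects the phase that
separates the processes, not the compressing one - which matches the
finding that extension mobility is unchanged.

## Specimen sampling

`sample_specimens()` draws per-specimen parameter sets: resting gap
N(39.9, 2.84) mm, total length tied to the gap through the arc-to-chord
ratio (with small jitter), DSP height, body scale, joint amplitudes
(sd 0.12 degrees), per-space amplitude jitter, and the desmotomy multiplier
(sd 0.06). Draws are truncated at 2.5 sd and rejection-sampled against the
most-flexed pose, because the stylized geometry has a finite articulation
envelope before adjacent vertebrae would interpenetrate. Two consequences
are documented limitations: the between-specimen ROM spread (~1.5-2 mm sd)
and the ROM-change spread (~0.5-1 mm sd) are smaller than the published
3.0 and 4.9 mm - reproducing those would require infeasible geometry - and
the total-length sd (~20 mm) is somewhat larger than the published 13.9 mm
because length is slaved to the sampled gap. A single integer seed makes a
whole simulated study bit-reproducible.

## Imaging model

`voxelize()` rasterizes the solids by vertical ray parity: exact occupancy
intervals along z, `partial_volume_supersampling`^2 = 9 lateral subcolumns
per voxel. Voxel HU is the occupancy-weighted mixture of bone (1500 HU),
soft tissue (40 HU, a 30 mm Euclidean-dilation envelope standing in for
musculature) and air (−1000 HU); the stochastic part is a zero-mean
Gaussian whose variance mixes the tissue variances (150, 30 HU sd) by
occupancy plus scanner noise (20 HU). `hu_model(noise = FALSE)` zeroes all
three, making the volume deterministic; with supersampling 1 the rasterizer
samples voxel centers, so the thresholded mask equals the reference label
grid exactly - the property the segmentation oracle tests rely on. Default
spacing is 0.5 mm isotropic (a bone-protocol reconstruction); simulated
studies default to 1.5 mm (below). No beam hardening, scatter or
reconstruction-kernel effects are modeled. Volumes read/write as NIfTI
(RNifti) or MetaImage (MET_DOUBLE), with the reference label grid in a
`_labels` companion file.

## Segmentation

`threshold_mask()` selects the +700..+3000 HU window, both ends inclusive.
`label_components()` finds 26-connected components above `min_voxels`,
relabels them cranial to caudal (descending centroid x), and - when the
expected count is missed, e.g. through noise bridging - applies one
morphological opening (3^3 box) before giving up with a diagnostic; the
manual mask editing of clinical workflows has no algorithmic analog, so an
automatic split plus an expected-count check replaces it.
`extract_surface()` closes each label (box closing, `wrap_radius` = 2
voxels; the "wrap" step) and triangulates the boundary of the binary field
at the voxel faces - a watertight surface whose vertices live on the voxel
corner lattice (voxel centers at 0-based index x spacing + origin).
`smooth_mesh()` applies Taubin lambda-mu smoothing (shrink 0.5, inflate
−0.526, 10 iterations), volume-preserving to within 1%; inside the
segmentation pipeline the total per-vertex displacement is additionally
clamped to one voxel diagonal, which enforces the contract that smoothing
never moves the surface by more than one voxel diagonal (unclamped
curvature flow violates this at sharp ridges). Landmarks are measured on
the *pre-smoothing* surface: smoothing exists for registration and surface
distances, and even bounded smoothing biases a ridge apex systematically
inward.

## Registration

`kabsch()` solves the weighted least-squares rigid alignment with the SVD
determinant correction; degenerate (collinear) configurations are rejected.
`icp()` aligns surfaces in two phases: point-to-point iterations on
area-uniform surface samples (nearest-neighbour correspondences, monotone
non-increasing RMS, asserted), then point-to-surface polishing with exact
closest points on triangles. The second phase matters: nearest-sampled-
neighbour ICP has a resolution floor of roughly the sampling spacing, while
the surface phase recovers synthetic displacements of a vertebra to better
than 0.01 mm and 0.01 degrees. Initialization aligns centroids and
principal axes; since principal-axis signs are arbitrary (and skewness-based
disambiguation is unstable for the near-symmetric mediolateral axis), all
four proper sign combinations are scored by nearest-neighbour RMS and the
best is kept. `superimpose_anchor()` registers each phase's T11 onto the
reference phase's T11 and applies that transform to the whole phase,
preserving within-phase geometry exactly (to rigid-motion precision);
`register_bone_across_phases()` then measures a bone's motion between
superimposed phases. The L1 flexion-to-extension excursion uses the
composition flexion -> resting -> extension, and its translation components
are reported at the moving bone's centroid ((R − I)c + t), which is the
origin-independent reading of a transform's translation; total rotation is
acos((tr R − 1)/2) and the mediolateral-axis rotation is the axis-angle
rotation projected on y. Both the transform-based excursion and the L1
Hausdorff distance are reported, as either could be the published
"maximal excursion".

## Simulated studies

`run_study()` chains everything: sample seven specimens, articulate each
into three phases pre and post desmotomy, apply a random scanner pose per
phase (rotation up to 4 degrees, translation up to 15 mm - this is what the
anchor superimposition must undo), voxelize at 1.5 mm, segment, superimpose,
measure. `imaging = FALSE` measures the articulated meshes directly (used
for statistical simulations). The 1.5 mm study resolution is the package's
standard phantom size: one seven-specimen imaging study is 42 volumes of
roughly 4-6 million voxels and runs in minutes; all voxel-based validation
tolerances are expressed in voxel diagonals and so scale with this choice
(at 1.5 mm, one voxel diagonal is 2.60 mm). Landmark recovery on the
imaging route is typically 1-2 mm (worst ~3.8 mm across a full study,
inside the 1.5-diagonal tolerance of 3.9 mm).

`analyze_study()` reproduces the statistical workflow: Shapiro-Wilk on the
paired differences gates each metric into a paired t test (mean +/- sd
summaries) or an exact Wilcoxon signed-rank (median (range)); the per-space
ROM table gets the within-subject two-way ANOVA (space x condition, subject
= specimen) with Greenhouse-Geisser correction for the 8-level space factor
reported alongside the uncorrected p-values, and Tukey HSD contrasts
against each effect's own error stratum; the resting comparison gets a
noncentral-t post-hoc power analysis. Percent changes are computed per
specimen and averaged (primary), with the group-means convention emitted
alongside - the two differ on heterogeneous baselines, which is why
published group means need not reproduce published percentages exactly.
Degenerate cases are defined: constant differences route nonparametric with
a warning, identical pre/post short-circuits to t = 0, p = 1, zero
differences are dropped by the Wilcoxon convention, and unbalanced ANOVA
tables are refused rather than imputed.

## What passing tests do and do not show

The phantoms validate the *measurement machinery*: segmentation recovers
the nine bones and their landmarks to voxel precision, registration
recovers known rigid motions, the measured ROM increase matches the
generating increase, the sign structure of the desmotomy effect (more
dorsoventral, craniocaudal and rotational mobility, extension unchanged)
is reproduced, and the statistical layer is calibrated (type-I error
0.03-0.07 at alpha 0.05; null ANOVA p-values uniform). They do not certify
the biology: real vertebrae are not extruded blocks, real joints are not
single-axis hinges about a fixed pivot, cadaveric loading includes soft
tissue and facet contact the phantom omits, and the generator's dispersion
is narrower than the biological one. Published magnitudes that the phantom
does not target (notably the global L1 translation excursions) are
reproduced qualitatively, not numerically.

## Reproducibility

Every stochastic step (specimen draws, imaging noise, scanner poses,
surface sampling) derives from one integer seed; rerunning a study or a
report with the same configuration is bit-identical. The acceptance script
(`scripts/acceptance.R`) regenerates the headline quantities from scratch;
`scripts/calibrate_defaults.R` re-derives the frozen joint-amplitude
defaults.
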