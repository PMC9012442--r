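# spinekin

In silico CT kinematics of the equine thoracolumbar spine under
interspinous ligament desmotomy (ISLD).

## The problem

"Kissing spines" (overriding dorsal spinous processes) is the most common
source of back pain in horses; ISLD — surgical transection of the
interspinous ligament — relieves pain, but its effect on spinal *mobility*
must be measured. The established in silico protocol images a T11–L1
segment (nine vertebrae, eight interspinous spaces) by bone-window CT in
resting, flexion and extension phases, before and after desmotomy of all
eight spaces; segments each vertebra by Hounsfield thresholding
(+700…+3000 HU); superimposes the phases rigidly on the T11 anchor; and
quantifies mobility locally and globally:

- **inter-DSP distance** `d_i = ‖x_i − x_{i+1}‖` between the craniodorsal
  landmark points of adjacent dorsal spinous processes;
- **per-space range of motion** `ROM_i = |d_i^flex − d_i^ext|`, averaged
  over spaces and specimens;
- **total length** `‖x_1 − x_9‖` (T11→L1);
- **L1 excursion** between flexion and extension: the rigid transform
  `T = T_ext ∘ T_flex⁻¹` of the anchor-superimposed L1, with translation
  read at the bone centroid, `(R − I)c + t`, decomposed into dorsoventral,
  craniocaudal and mediolateral components; rotation
  `θ = acos((tr R − 1)/2)` and its mediolateral-axis projection; and the
  symmetric Hausdorff distance between the two L1 surfaces;
- a paired statistical workflow: Shapiro–Wilk normality gate, paired
  t-test / Wilcoxon signed-rank, within-subject two-way ANOVA
  (space × condition) with Greenhouse–Geisser correction and Tukey HSD,
  and noncentral-t power analysis.

`spinekin` implements that pipeline end to end **on synthetic spine
phantoms with known kinematics**, so every step — voxelization,
segmentation, rigid registration (Kabsch/ICP), measurement, statistics —
is validated against ground truth. It is aimed at researchers developing
or auditing CT-based skeletal kinematics workflows.

## Worked example

```r
library(spinekin)

# the published worked example: per-space ROM rises 17.9 -> 23.5 mm
summarize_effects(17.9, 23.5, "rom")$change
#> [1] 5.6

# a complete simulated study: 7 specimens, 3 phases x 2 conditions each,
# voxelized at 1.5 mm, segmented and registered back (runs for some minutes;
# imaging = FALSE measures the phantom meshes directly in seconds)
st <- run_study(study_config(n_specimens = 7, seed = 42, imaging = FALSE))
st
#> isld_study: 7 specimens, ground-truth mesh route, spacing 1.5 mm
#>   mean per-space ROM: pre 17.3 mm, post 22.7 mm

an <- analyze_study(st)
print(an$tests$rom)
#> Wilcoxon signed-rank: statistic 28, p = 0.01563 * (effect size d = 10.5)
#>   pre 17.7 (14.9-18.5), post 23.4 (19.9-24.8) [nonparametric route]
```

The numbers mean: in this simulated study the mean per-space range of
motion rose from 17.3 to 22.7 mm after desmotomy (the generator is
calibrated to 17.9 → 23.5 mm; individual studies scatter around those
values), the Shapiro–Wilk gate routed this sample's differences to the
exact Wilcoxon signed-rank test, and no-effect is rejected at p ≈ 0.016
(the smallest p the exact test can produce at n = 7). `build_report()`
writes the measurement tables (CSV), the effect/test/ANOVA summary (JSON)
and a log, bit-identically for a fixed seed.

The individual stages are exported too: `build_template()`,
`articulate()`, `voxelize()`, `threshold_mask()`, `label_components()`,
`extract_surface()`, `smooth_mesh()`, `kabsch()`, `icp()`,
`superimpose_anchor()`, `craniodorsal_landmark()`, `hausdorff_distance()`,
`decompose_motion()`, `paired_compare()`, `rm_anova_spaces()`,
`power_paired()`. See the methods vignette
(`vignettes/spinekin-methods.Rmd`) for the model, its assumptions and its
limitations.

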