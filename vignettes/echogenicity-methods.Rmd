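---
title: "Differential echogenicity: method, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential echogenicity: method, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivusecho)
```

## The measurement model

B-mode IVUS grey levels are not calibrated: they depend on the transducer,
the console's gain curve and the tissue path. Differential echogenicity
turns them into a usable tissue score by referencing every pixel to the
brightness of the adventitia of the same vessel — the dense connective layer
just outside the external elastic membrane (EEM), which is reliably the
brightest ordinary tissue in the image. Wall pixels darker than the
adventitial median are called hypoechogenic, brighter ones hyperechogenic,
and a second, high-intensity threshold separates strongly reflecting
structures (polymer struts, calcium) from the bright tail of ordinary
tissue. Acoustic physics supplies the final split: calcium both reflects and
attenuates, so a truly calcified region casts a dark radial shadow behind
itself, while bright tissue and polymer struts do not. The five classes are
therefore hypo, hyper, upper (bright, no shadow), calcified (bright, with
shadow) and unknown (the shadow itself, where the signal carries no tissue
information).

The analysis assumes: (i) closed lumen / scaffold / vessel contours are
supplied per analyzed frame (tracing is semi-automatic upstream work, not
part of this package); (ii) frames are 8-bit square grids with isotropic
pixel spacing and a known catheter center; (iii) the adventitia is bright
*except* where something identifiable obscures it, which is exactly what the
sector-exclusion step removes.

## Pipeline and tunable parameters

`analyze_pullback()` executes, per frame:

1. **Ring construction** — pixels outside the vessel polygon whose Euclidean
   distance to the polygon boundary lies in [`ring_dmin_mm`, `ring_dmax_mm`]
   (defaults 0.01 and 0.21 mm). Distances are measured to the polygon
   segments themselves, not to a circle fit, because real EEM contours are
   irregular.
2. **Adaptive exclusion** — Otsu's threshold over the whole ring, then 2°
   sectors (`sector_deg`) anchored at the catheter center, counterclockwise
   from the positive column axis. A sector is dropped when *strictly more
   than half* of its pixels are *strictly below* the threshold, when it
   intersects a user-supplied guidewire interval, or when it contains no
   ring pixels. Both strictness choices are deliberate, documented
   conventions so that independent re-implementations can match exactly.
3. **Pooling** — retained histograms are summed over frames; the global
   hypo/hyper threshold is the pooled *lower median* (smallest grey level
   whose cumulative count reaches half the total). An integer median is
   required because it is used as a grey-level threshold.
4. **High threshold** — three-stage iterated Otsu on the full frame
   histogram (each stage restricted to levels strictly above the previous
   threshold). Per-pullback combination is the lower median of per-frame
   values (`high_mode = "median"`); a pooled-histogram mode exists because
   the per-frame/per-pullback scope is a genuinely open point in the
   method's description. If a stage sees fewer than two populated levels the
   previous threshold is returned with a `saturated-iteration` warning. If
   the high threshold falls below the reference median (possible on
   pathological frames) it is clamped up to it, with a warning
   (`clamp_high`).
5. **Classification** — within the total wall: grey < median → hypo,
   otherwise hyper; the equal-to-median tie goes to hyper so the two classes
   partition (`tie` flips it). Pixels strictly above the high threshold form
   8-connected components (2-D only; no 3-D linking across frames).
6. **Shadow detection** — the method's published description names an
   in-house algorithm without internals, so this component is this package's
   own design: rays from the catheter center through every angular position
   covered by the component (each pixel's angular footprint, ≈1/r rad, keeps
   thin arcs fully covered), sampling from just beyond the component's outer
   edge to `shadow_depth_mm` (0.5 mm). The component is calcified when the
   pooled mean of the behind-region is below `shadow_fraction` (0.25) of the
   reference median. Shadow pixels within the wall become unknown; the
   shadow decision flips exactly at the configured fraction, which the test
   suite sweeps.
7. **Volumetrics** — rectangular-rule integration: class area × frame
   spacing, summed over analyzed frames, matching the standard fixed
   0.5 mm analysis interval; percentages are per-compartment shares, and
   `normalize_by_mean_length()` rescales volumes to a cohort mean length
   (16.5 mm in the porcine degradation setting) without touching
   percentages.

Compartment masks use the even-odd rule at pixel centers with a half-open
boundary convention (an axis-aligned square of side 10 covers exactly 100
pixels). Both compartments are clipped by the lumen: where the scaffold
contour dips inside the lumen, the pixels between them are lumen, not wall,
and belong to no compartment.

## Statistics

`pearson_r()`, `linreg()` and `anova_oneway()` delegate to the standard R
fitting machinery. `icc()` computes single-measure ICCs from the two-way
crossed ANOVA mean squares; the default ICC(2,1) (two-way random effects,
absolute agreement) is the standard choice for method agreement in imaging,
with ICC(3,1) available where a fixed reader offset should not be
penalized. `ward_cluster()` implements Ward linkage via the Lance–Williams
update on squared Euclidean distances with a fixed tie rule (merge the
lowest-index pair), making the merge tree fully deterministic; its stored
heights equal twice the within-cluster sum-of-squares increase of each
merge, and the suite verifies the whole tree against exhaustive
minimal-WSS-increase merging.

## The phantom: what it emulates, and what it does not

`phantom_pullback()` renders concentric, sinusoidally perturbed tissue
layers (blood 15, neointima/media 45, adventitial band 180, background 25 on
the 0–255 scale), hyperechogenic strut blocks between the scaffold and
vessel contours, an optional low-intensity wedge over the adventitia (the
pericardium / side-branch analogue) and an optional calcified arc whose
shadow zeroes everything radially behind it. Speckle is multiplicative
Rayleigh, blended toward its mean by `speckle_amp` (default 0.35): fully
developed speckle (amplitude 1) has so heavy a left tail that no adventitia
could serve as a reference, whereas scan-converted, post-processed B-mode
exports show exactly this kind of tamed texture. Strut brightness is
`strut_peak × f(Mw)` with `f` linear from 0 at Mw = 0 to 1 at `mw_ref`
(92.9 kDa, the 1-month mean of the porcine Absorb series); a sigmoid
alternative is provided. This mapping is a stand-in — the brightness–Mw
link is an empirical observation, not a physical law — so phantom-based
correlation results demonstrate *recovery of a planted monotone signal*,
not the in-vivo effect size.

The phantom does not emulate: ultrasound wave propagation (no Field-II
class simulation), catheter eccentricity artifacts, NURD, blood speckle
decorrelation, ECG-phase motion, or atherosclerotic plaque. Passing tests
therefore show the algorithm chain is correct and stable under controlled
degradation of its inputs, not that it would reproduce animal-study values.

Default problem sizes keep the whole suite desk-scale: 128 px frames at
0.03 mm/px, 5–7 frames per pullback, and a degradation cohort of 3 scaffolds
× 9 timepoints (molecular weight schedule 92.9, 84.2, 76, 47.1, 26.2, 7.9,
4.7, 3.9, 0 kDa) across 20 seeds for the correlation-recovery property.

## Numerical choices and degenerate inputs

* Otsu ties break toward the smallest maximizing threshold; histograms with
  fewer than two populated levels are rejected as degenerate.
* A single-valued reference ring (possible only in noiseless synthetic
  input) skips adaptive exclusion and keeps all sectors.
* An empty pooled reference (all sectors excluded in every frame) aborts
  the pullback with a `no-reference` error rather than guessing a median.
* Components touching the image border with no assessable behind-region are
  non-shadowed by definition, with a warning.
* Zero-area compartments report `NA` percentages with a warning rather than
  dividing by zero.
* All randomness flows through explicit seeds; a fixed seed reproduces
  frames and result files byte for byte.

## Discrimination contrast for the shadow test

With speckled struts, the third Otsu stage necessarily cuts *inside* the
brightest intensity cluster — it is a variance maximizer, and whatever
remains above the second threshold gets split. Per-pixel recall of the
upper class against planted truth is therefore evaluated at a configured
noiseless contrast: four exact intensity modes (wall 90, adventitia 180,
struts and calcium saturated at 255) peel off one per stage, the saturated
top class triggers the documented saturation path, and struts are placed
angularly clear of the calcified arc so 8-connected components stay
distinct. The speckled defaults remain in force for every other property,
including the end-to-end correlation recovery.

## Known limitations

* Contour quality bounds everything: the package validates simplicity and
  nesting but cannot detect tracing errors.
* The shadow detector is a reasonable geometric design, not a reproduction
  of the original in-house algorithm; its two parameters are exposed and
  their boundary behavior is pinned by tests.
* The high-threshold pooling scope (per frame vs per pullback) changes
  results on heterogeneous pullbacks; both modes are exposed and the choice
  is recorded in every output bundle.
* Volumes use the rectangular rule; Simpson-type integration would differ
  for rapidly varying lumens but is not what fixed-interval IVUS practice
  uses.
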