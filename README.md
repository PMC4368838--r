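# ivusecho

Differential echogenicity analysis of intravascular ultrasound (IVUS)
pullbacks, for quantifying the degradation of bioresorbable vascular
scaffolds (BRS).

## The problem

Polymeric scaffolds (e.g. poly-L-lactide) implanted in coronary arteries
degrade over months to years. Their struts appear as bright, hyperechogenic
blocks in B-mode IVUS, and the brightness fades as the polymer's molecular
weight falls. Quantifying "how bright the scaffolded wall is" therefore
offers a non-destructive surrogate for chemical degradation assays — but raw
grey levels depend on the transducer, gain settings and the individual
vessel, so the measurement must be normalized to an internal reference.

`ivusecho` implements the adventitia-referenced classification that solves
this. For each cross-section with traced lumen, scaffold and vessel (EEM)
contours:

1. **Reference adventitia.** The ring of pixels 0.01–0.21 mm outside the
   vessel contour is the brightness reference. Otsu's adaptive threshold
   (maximizing the between-class variance σ²_B(t) = ω₀ω₁(μ₀−μ₁)²) is computed
   on the ring, the ring is divided into 2° sectors, and any sector in which
   more than half the pixels fall below the threshold — pericardium, side
   branches, guidewire shadow — is excluded.
2. **Global thresholds.** The retained per-frame histograms are pooled over
   the pullback; their median grey level *m* splits **hypo**- from
   **hyper**echogenic wall tissue. A high-intensity threshold *h* comes from
   three-stage iterated Otsu on the frame histogram (each stage re-applies
   Otsu to the levels above the previous threshold).
3. **Five-class labeling.** Within the wall: grey < *m* → hypo; *m* ≤ grey ≤
   *h* → hyper; grey > *h* forms connected highly echogenic components. A
   radial shadow detector (mean brightness behind the component below a
   fraction of the reference median) splits these into **upper**echogenic
   (no shadow) versus **calcified** with its shadow labeled **unknown**.
4. **Volumetrics.** Class areas are integrated over the analyzed frames
   (0.5 mm apart) into volumes and percentages per compartment
   (lumen–scaffold, scaffold–vessel, total wall), plus lumen / scaffold /
   vessel / neointima (= vessel − lumen) volumes, with optional
   normalization to the cohort mean scaffold length.
5. **Statistics.** Pearson correlation and linear regression of
   high-echogenicity volume against molecular weight, Ward clustering
   (squared Euclidean distance) of (hyper+upper, hypo) volumes, one-way
   ANOVA, and ICC(2,1)/ICC(3,1) for reader agreement.

Because no acquired IVUS data ship with the package, a synthetic phantom
generator (`phantom_pullback()`, `degradation_cohort()`) renders speckled
layered cross-sections with matching contours and ground-truth labels,
including strut brightness tied to molecular weight, dark wedges over the
adventitia and calcified arcs casting shadows.

## Worked example

```r
library(ivusecho)

cf  <- phantom_config(n_frames = 5, mw = 92.9, seed = 42)  # fresh scaffold
ph  <- phantom_pullback(cf)
fit <- analyze_pullback(ph$frames, ph$contours,
                        ph$meta$pixel_spacing_mm, ph$meta$frame_spacing_mm)
fit
```

```
Differential echogenicity analysis
  frames analyzed      : 5 (2.5 mm at 0.50 mm spacing)
  reference median     : 190 (pooled adventitia, 2882 px)
  high threshold       : 226 (median of per-frame iterated Otsu)
  volumes (mm^3)       : vessel 18.9, lumen 7.9, scaffold 12.3, neointima 11.0
  total wall composition:
    hypo         10.13 mm^3   91.9 %
    hyper         0.25 mm^3    2.3 %
    upper         0.64 mm^3    5.8 %
    calcified     0.00 mm^3    0.0 %
    unknown       0.00 mm^3    0.0 %
```

The adventitial reference median of this pullback is grey level 190; the
8 bright struts push ~8 % of the wall above it (hyper + upper), almost all
of it in the scaffold–vessel compartment (0.89 mm³). Re-running with a lower
`mw` dims the struts toward the wall speckle and that volume falls toward
zero — the degradation signal. `summary(fit)` prints the full compartment ×
class table and per-frame reference diagnostics; `plot(fit, frame = 1)`
shows the label map.

A shell front end wraps the same functions:

```sh
Rscript inst/cli/ivusecho.R phantom --output pb --seed 1
Rscript inst/cli/ivusecho.R analyze --input pb --output results_pb
Rscript inst/cli/ivusecho.R stats --volumes cohort.csv --mw mw.csv --output report
Rscript inst/cli/ivusecho.R reproducibility --readings readings.csv --output repro
```

## Documentation

The methods vignette (`vignettes/echogenicity-methods.Rmd`) describes the
model, its parameters and defaults, what the phantom does and does not
emulate, and the package's design choices at the points the method leaves
open.
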