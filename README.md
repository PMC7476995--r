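# marrowdiff

A desk-scale R toolkit for the digital-morphology workflow behind
automated bone-marrow aspirate smear analysis. The bone-marrow
differential count — tallying nucleated marrow cells by type and
reporting each lineage's percentage — is a cornerstone of hematologic
diagnosis, and automating it requires a chain of image-analysis and
validation steps that this package implements end to end on synthetic
data with exact ground truth:

- **Synthetic smear generation** — Wright-Giemsa-like fields (pale
  background, anucleate red-cell discs, nucleated cells drawn from 12
  phenotype classes with class-specific nucleus shape, colour and N:C
  ratio), defocus z-stacks, and paired two-method differential-count
  tables with configurable bias and noise. Every raster comes with
  per-cell ground-truth masks.
- **Autofocus** — a two-stage search over a z-stack restricted to a
  white-cell region of interest: coarse stage scored by the luminance
  variance (mean square deviation), fine stage by the Canny edge-pixel
  fraction.
- **Localization & segmentation** — grayscale k-means to find nucleated
  cells (darkest cluster, morphology, area/circularity gates), then
  colour k-means in YCbCr with a fixed decision cascade labelling each
  crop pixel as background / RBC / cytoplasm / nucleus.
- **Classification** — interpretable morphology features (areas, N:C
  ratio, circularity, lobedness, eccentricity, per-compartment colour,
  chromatin texture) feeding a pluggable 12-category probabilistic
  classifier (default: seeded, class-weighted random forest) that emits
  the full ranking and the top-5 most likely classes per cell.
- **Differential reporting** — aggregation into the five reporting
  series (granulocytes, erythroid, lymphoid, monocytes, plasma cells)
  with the G:E ratio; "other" is counted but excluded from the
  percentage denominator.
- **Method-comparison statistics** — multiclass confusion metrics with
  binomial CIs; the two-way consistency intraclass correlation
  ICC(C,1) = (MSR − MSE)/(MSR + (k−1)·MSE) with F-based confidence
  bounds, including the closed form from a printed F ratio alone
  (for k = 2, ICC = (F−1)/(F+1)); Passing-Bablok regression (K-shifted
  median of all pairwise slopes, rank-based CIs, cusum linearity test);
  and Bland-Altman limits of agreement bias ± 1.96·SD with CIs.

The methods vignette (`vignettes/methods.Rmd`) documents the models,
parameter defaults, numerical choices, and what synthetic validation
does and does not demonstrate.

## Worked example

Train a classifier on the default synthetic corpus, render eight mixed
fields, and run the full analyze pipeline:

```r
library(marrowdiff)

model <- run_train(list(seed = 42, n_per_class = 40))
round(model$holdout_accuracy, 3)
#> [1] 1

freq <- c(myeloblast = 2, promyelocyte = 3, myelocyte = 6, metamyelocyte = 8,
          neutrophil = 28, eosinophil = 2, basophil = 1, monocyte = 3,
          erythroblast = 28, lymphocyte = 14, plasma_cell = 2, other = 3)
res <- run_analyze(list(out_dir = "demo_out", model = model, seed = 7,
                        n_fields = 8,
                        field = list(n_nucleated = 15,
                                     class_frequencies = freq)))
nrow(res$cells)                 # 119 nucleated cells detected
round(res$report$series_pct, 1)
#> granulocytes    erythroid     lymphoid    monocytes plasma_cells
#>         44.1         36.4         11.9          5.1          2.5
round(res$report$ge_ratio, 2)
#> [1] 1.21
```

The report says: of the counted nucleated cells (excluding "other"),
44.1% were granulocytic, 36.4% erythroid, and so on, with 1.21
granulocytic cells per erythroblast — a left-shifted, erythroid-rich
marrow by construction of `freq`. `demo_out/` holds the report JSON/CSV
and a per-cell table with each cell's box and top-5 ranking.

Method-comparison statistics work directly from printed summary values
as well as raw data; for example, auditing a published per-series F
ratio (two methods, 124 smears):

```r
r <- icc_from_f(17.748, n_subjects = 124, k_raters = 2)
sprintf("ICC %.3f (95%% CI %.3f-%.3f)", r$icc, r$ci[1], r$ci[2])
#> [1] "ICC 0.893 (95% CI 0.851-0.924)"
```

A thin CLI over the same functions lives at `inst/scripts/marrowdiff`
(`simulate | train | analyze | evaluate`, each driven by a YAML/JSON
config).

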