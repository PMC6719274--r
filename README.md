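# ctiic — acute infarct volumetry on noncontrast head CT

Early ischemic infarcts on noncontrast head CT (NCCT) are shallow regional
hypodensities — often only 1–4 HU below normal brain in the first hours,
near or below the limit of what a reader can see, and without a boundary
that manual ROI tools, edge detection or region filling could latch onto.
`ctiic` is an R package for radiology image-analysis researchers that turns
this weakness into the measurement principle: to an intensity-inhomogeneity
correction (IIC, "bias field") algorithm, a broad shallow hypodensity looks
like shading, so the correction field itself reveals and quantifies the
lesion.

## Method

For a brain-extracted input volume $v$ (HU), an IIC backend produces a
"restored" image $\hat v$ in which slowly varying intensity nonuniformity
has been removed. The difference map

$$d = v - \hat v \qquad \text{(HU, zero-mean over the brain mask)}$$

contains the baseline corrections (chiefly the skull-induced "cupping"
depression) *and* the absorbed part of any infarct. The map is split into
hemispheres at the brain-mask midline, thresholded at an upper value of
−1.5 HU, and the infarct volume estimated by contralateral subtraction:

$$V_\text{infarct} = V_\text{ipsi}(d \le -1.5\,\text{HU}) - V_\text{contra}(d \le -1.5\,\text{HU}),$$

which cancels the left–right-symmetric artifact baseline. Two IIC backends
are provided: `em_seg`, an EM Gaussian-mixture segmentation with an
interleaved Gaussian-smoothed bias field, and `hist_sharpen`, a
multiresolution histogram-sharpening corrector (Wiener deconvolution of the
log-intensity histogram, B-spline field fit). A synthetic head-CT phantom
generator (ellipsoidal brain in a skull shell, quadratic cupping, Gaussian
noise, spherical or territory-shaped lesions of exactly known volume and
fractional density reduction) makes the whole pipeline testable without
clinical data.

## Worked example

```r
library(ctiic)

# a control head phantom with one right-sided 45 cc sphere at 20% density
# reduction (34 HU brain -> 6.8 HU contrast)
truth  <- make_head_phantom(phantom_spec(seed = 1))
lesion <- lesion_spec("sphere", center = c(34, 0, 0), target_volume = 45,
                      density_reduction = 0.20, side = "right")
truth  <- insert_lesion(truth, lesion)
truth$lesion_volume_true
#> [1] 44.85938

report <- run_pipeline(truth$image, backend = "hist_sharpen", side_ipsi = "right")
report
#> <volume_report> backend hist_sharpen, ipsi right
#>   ipsi 81.86 cc - contra 13.10 cc = infarct 68.77 cc (threshold -1.5 HU)
```

The true inserted volume is 44.9 cc (voxelised 45 cc sphere). The
ipsilateral hemisphere holds 81.9 cc of sub-threshold correction — the
absorbed lesion plus its share of the symmetric cupping baseline — the
contralateral hemisphere 13.1 cc of baseline only, and the subtraction
yields 68.8 cc. Overestimation at this size and contrast is expected: the
smooth field spreads the lesion's footprint, and recovery ratios improve
with increasing lesion size (see the recovery study below). A mere 10%
density reduction (≈3 HU), invisible on the image itself, still produces a
measurable ipsi–contra difference.

The full recovery study (3 sizes × 4 contrasts × 2 backends on a shared
control phantom) runs with:

```r
grid <- run_grid(grid_spec(seed = 1))
summarize_ratios(grid)     # recovery-ratio tables, one per backend
grid_correlations(grid)    # Pearson r of measured vs true volume per contrast
```

A thin command-line interface wraps the same functions
(`exec/ctiic phantom|extract|correct|volume|simulate`); each subcommand
reads and writes NIfTI-1, YAML specs and JSON/CSV reports.

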