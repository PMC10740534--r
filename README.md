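# blob3d

Detection and segmentation of small dark blobs in 3D grayscale volumes —
the kind of densely scattered, few-voxel objects that carry imaging
biomarkers, such as glomeruli in cationic-ferritin-enhanced MRI (CFE-MRI),
where the total count N<sub>glom</sub> per kidney quantifies renal
filtration capacity. Blobs at this scale resemble noise, and voxel-level
labels for supervised learning are effectively unobtainable, so the package
implements a label-free pipeline:

1. **Phantom synthesis.** Clean 3D blob images with exact ground truth from
   elliptical Gaussians
   F(x,y,z) = A·exp(−(ax² + by² + cz² + dxy + eyz + fxz)), the six
   coefficients driven by orientation angles (θ, φ) and per-axis scales
   (σ<sub>x</sub>, σ<sub>y</sub>, σ<sub>z</sub>); calibrated Gaussian noise
   with σ²_noise = σ²_image / 10^(SNR/10).
2. **Hessian convexity analysis.** A voxel is peak-like when the 3×3
   central-difference Hessian of the inverted image J − f is negative
   definite (Sylvester's criterion); the indicator over the volume is the
   Hessian convexity mask. Blobness = 3·|det H|^(2/3) / pm(H), with pm the
   sum of 2×2 principal minors, is a scale-free shape score in (0, 1] that
   equals 1 only for isotropic curvature.
3. **Unpaired contrastive translation (denoising).** A one-sided 3D
   image-to-image translation model — encoder–decoder generator with
   residual blocks, volumetric PatchGAN discriminator — trained with
   adversarial, patchwise-contrastive (PatchNCE), convexity-consistency and
   intensity-distribution (KL) losses, maps noisy volumes into the clean
   phantom domain without paired data. The network engine (3D convolutions,
   backpropagation, Adam) is implemented in the package with compiled
   kernels.
4. **Identification.** Final mask = convexity mask ⊙ thresholded
   translation (Hadamard product); 26-connected components give counts,
   centroids and per-blob blobness.
5. **Evaluation.** DER, greedily matched precision/recall/F-score (distance
   threshold = average ground-truth blob diameter), Dice, IoU, mean
   blobness; per-image reports aggregate as mean ± SD.

Results come back as tibbles with `tidy()`/`glance()` methods and
`autoplot()` visualizations; see the methods vignette
(`vignettes/blob-detection-methods.Rmd`) for the models, assumptions and
design decisions.

## Worked example

```r
library(blob3d)

ph <- compose_phantom(shape = c(32, 32, 16), n_blobs_range = c(8, 12), seed = 42)
print(ph)
#> <phantom> 32x32x16 voxels, 8 blobs (composite = max, seed = 42)

noisy <- add_noise(ph$image, snr_db = c(0.01, 1), seed = 43)
det <- detect(noisy, model = NULL)   # identity translation: convexity + intensity
print(det)
#> <blob_detection> 6 blobs (26-connectivity, min size 2 voxels)

report <- evaluate_run(det, ph)
tidy(report)
#> # A tibble: 7 × 2
#>   metric        value
#>   <chr>         <dbl>
#> 1 der           0.25
#> 2 precision     1
#> 3 recall        0.75
#> 4 f_score       0.857
#> 5 dice          0.625
#> 6 iou           0.455
#> 7 mean_blobness 0.893
```

The phantom holds 8 blobs; without a trained translator (identity
translation) the convexity–intensity intersection already finds 6 of them
with no false positives under noise whose variance is comparable to the
image variance (SNR 0.01–1 dB): precision 1, recall 0.75, detection error
rate 0.25. Dice/IoU compare the identification mask with the ground-truth
mask voxelwise; mean blobness near 0.9 says the detected objects have
nearly isotropic curvature. Training a translator first
(`train_translator()`, or the complete seeded CPU-scale study
`smoke_experiment()`) raises F-score above this baseline by removing noise
components before the intersection:

```r
res <- smoke_experiment(seed = 7)       # ~2 min on one CPU
autoplot(res$model)                     # per-epoch loss curves
summarise_metrics(res$reports)          # mean ± SD across validation volumes
```

A thin command-line interface over the same functions is at
`inst/cli/blob3d.R` (subcommands `synth`, `train`, `translate`, `detect`,
`eval`, `pipeline`), reading and writing NIfTI/TIFF volumes, CSV blob
tables and JSON manifests.

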