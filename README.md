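# arkfcm

Adaptively regularized kernel-based fuzzy C-means (ARKFCM) clustering for
segmenting grayscale brain MR images into tissue classes (CSF, GM, WM),
with evaluation metrics and a synthetic phantom generator.

## Who this is for

Researchers segmenting T1-weighted brain slices (or any scalar image with a
few intensity modes) who need a soft clustering method that is robust to
noise without a hand-tuned neighborhood-influence parameter, plus the
tooling to validate it: ground-truth phantoms, Jaccard scores, and a
ground-truth-free entropy quality measure.

## The method

Fuzzy C-means assigns each pixel `i` a membership `u_ij` in every cluster
`j` and minimizes a fuzzified within-cluster dissimilarity. This package
replaces the squared Euclidean distance with the GRBF kernel dissimilarity
`2(1 − K(x, v))`, `K(x, v) = exp(−(x−v)²/2σ²)`, and adds a spatial term
weighted per pixel by an adaptive regularizer `φ_i`:

    J = 2 Σ_i Σ_j u_ij^m (1 − K(x_i, v_j))
      +   Σ_i Σ_j φ_i u_ij^m (1 − K(x̄_i, v_j))

`φ_i ∈ {0} ∪ (2−ω_i, 2+ω_i)` is derived from the local variation
coefficient (window variance normalized by squared window mean): pixels in
heterogeneous (noisy) neighborhoods receive strong context, pixels that
already equal their window mean receive none. `x̄_i` is a smoothed image —
local mean (**ARKFCM₁**), local median (**ARKFCM₂**), or a devised weighted
image (**ARKFCM_w**) — computed once before iteration, which keeps the cost
per iteration at plain-FCM levels. `σ` is estimated from the dispersion of
pixel-to-mean distances, making results invariant to affine intensity
rescaling. Baseline FCM (`fcm_segment()`) is included for comparison.

## Worked example

```r
library(arkfcm)

spec <- phantom_spec(shape = c(128, 128), geometry = "slice_like",
                     noise_model = "rician", noise_level = 10, seed = 7)
ph  <- generate_phantom(spec)
seg <- arkfcm_segment(ph$image, cluster_config(3, variant = "median"))
seg
#> <segmentation_result: 3 clusters, variant=median, 7 iter (converged), sigma=23.15>
#> centers: 52.74, 106.9, 153.7

round(jaccard_scores(seg$labels, ph$truth$labels), 3)
#>       1       2       3 average
#>   0.987   0.992   0.993   0.991

round(entropy_E(ph$image$pixels, seg$labels), 3)
#> [1] 5.32
```

The phantom is a brain-like slice (true tissue means 48/106/154) under 10%
Rician noise. The converged centers (52.7/106.9/153.7) sit close to the
true means — the CSF center is biased upward because Rician noise inflates
dark-tissue magnitudes. Labels are coded 0 = background and 1..3 in
ascending center order (CSF, GM, WM on T1 contrast); per-class Jaccard
scores near 0.99 mean almost perfect overlap with ground truth, and the
entropy measure `E` (lower is better at a fixed number of regions)
evaluates segmentation quality without ground truth.

## Command line

```sh
Rscript -e 'arkfcm::arkfcm_cli()' phantom --output-dir out --shape 128x128 \
    --noise gaussian --noise-level 7 --bias 0.2 --seed 1
Rscript -e 'arkfcm::arkfcm_cli()' segment --input out/phantom.png \
    --output-dir out/seg --variant median
Rscript -e 'arkfcm::arkfcm_cli()' evaluate --pred out/seg/phantom_labels.png \
    --truth out/phantom_truth.png --image out/phantom.png --output-dir out
```

`segment` writes the label map and a JSON run report (σ used, iterations,
objective trace, per-iteration membership change); `evaluate` writes
metrics as JSON and CSV. The same commands are available in-process as
`cmd_phantom()`, `cmd_segment()`, `cmd_evaluate()`.

## Documentation

The methods vignette (`vignettes/arkfcm-methods.Rmd`) describes the model,
the numerical choices (boundary policy, softmax stabilization, singularity
handling, initialization), what the phantom generator does and does not
emulate, and the package's known limitations.
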