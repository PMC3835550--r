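# tvcount

Automatic counting of darkly labeled cell somata — typically DAB-stained
cone photoreceptors in retinal wholemount micrographs — from single-channel
grayscale images. Manual counting of photoreceptor mosaics is slow and
needs trained observers; naive intensity thresholding fails on real
micrographs because the background brightness is uneven ("blotchy"), and
debris, vessels or co-labeled cell types add spurious dark features.
`tvcount` implements a four-step, fully traceable pipeline for biologists
who need reproducible cell-density data, plus a ground-truthed synthetic
phantom generator for validating it.

## The method

For an image `I0` with intensities in [0, 1] (dark cells on a bright
field):

1. **Background homogenization.** Subtract the `m × m` median-filtered
   image: `I1 = ((I0 − medfilt(I0, m)) + 1) / 2`. Slow background
   fluctuations are removed; the result has a neutral background near 0.5.
2. **Total-variation denoising.** Solve the Rudin–Osher–Fatemi problem

   ```
   min_x  ½ ‖x − I1‖² + α |x|_TV
   ```

   with a first-order primal–dual (Chambolle–Pock) iteration run for
   exactly `N` steps (dual ascent on the forward-difference gradient,
   projection of the dual field onto the pointwise α-ball, proximal
   primal step, over-relaxation). The output is a cartoon-like image in
   which labeled somata survive as flat dark spots while noise and fine
   texture are flattened.
3. **Statistical thresholding.** A pixel is "black enough" to belong to a
   cell when `x_ij < mean(x) − c · sd(x)` (sample standard deviation over
   all pixels of the image being thresholded). The rule is invariant
   under positive affine rescaling of intensities.
4. **Counting.** Connected components (8-adjacency by default) of the
   mask with at least `f` pixels are counted; their centroids are the
   reported cell positions.

Only `m`, `c` and `f` normally need calibration on one representative
image; defaults are `m = 30`, `c = 2.5`, `f = 5`, `α = 0.05`, `N = 50`.
Two baseline modes used for method comparison are built in: `direct`
(steps 3–4 on the raw image) and `median_direct` (steps 1, 3, 4).

## Worked example

```r
library(tvcount)

# a 512x512 phantom: 100 dark somata (radius 4 px, contrast 0.4) on a
# blotchy background (sd 0.15, correlation length 60 px), pixel noise 0.02
ph  <- generate_phantom(phantom_spec(n_spots = 100, seed = 42))
res <- run_pipeline(ph$image, pipeline_params())
res
#> <count_result> mode = tv | count = 100 of 100 components (f = 5)

glance(res)
#> # A tibble: 1 × 8
#>   count n_components n_discarded mode  threshold     m     c     f
#>   <int>        <int>       <int> <chr>     <dbl> <int> <dbl> <int>
#> 1   100          100           0 tv        0.442    30   2.5     5

head(tidy(res), 3)           # one row per counted cell
#> # A tibble: 3 × 4
#>      id   row   col  size
#>   <int> <dbl> <dbl> <int>
#> 1     1  13.7  275.    54
#> 2     2  16.6  166.    53
#> 3     3  28.3  316.    53

evaluate_detection(res, ph$truth)
#>   n_true n_detected n_matched recall_percent artifact_percent relative_error
#> 1    100        100       100            100                0              0
```

All 100 true somata are found (recall 100%), nothing spurious is counted
(artifacts 0%), and the count matches the ground truth exactly
(relative error 0%). The `threshold` column shows the automatic cut,
mean − 2.5 sd ≈ 0.442, applied to the denoised image.
`autoplot(res)` overlays the counted centroids on the image;
`save_overlay()` writes the classic red-overlay PNG.

## Batch use and the command line

```r
report <- run_batch(files, pipeline_params(pixel_pitch_um = 1.2))
write_batch_report(report, "report.csv")   # + report_positions.csv
```

The report lists count, density (cells/mm², when a pixel pitch is given)
and positions per file; `save_config()`/`load_config()` persist the
parameter set and file list as YAML. The same workflow is available from
a shell via the thin wrapper installed at `inst/cli/count.R`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/count.R", package = "tvcount"))')
Rscript $CLI phantom --seed 5 --n 3 --out phantoms/
Rscript $CLI run phantoms/*.png --pitch-um 1 --out report.csv
Rscript $CLI eval --report report.csv --truth phantoms/phantom_seed005_truth.csv \
                  --file phantoms/phantom_seed005.png
```

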