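# stalkscan

Counting banana plants and measuring pseudo-stem diameter and height from
terrestrial laser scanning (TLS) point clouds of closed-canopy plantations.

Plantation management needs per-plant morphometry — the number of plants, and
the diameter and height of each pseudo-stem — but manual measurement takes
minutes per plant and field scans of a closed canopy are hard to separate into
individual plants: leaves interlock, bamboo support poles stand next to stems,
and broken leaves hang low in the understory. stalkscan implements a
geometric pipeline that works directly on a co-registered, metric, Z-up point
cloud of a whole plot:

1. **Preprocess** — voxel downsampling (8 mm leaf), statistical outlier
   removal (k = 50 nearest neighbours, mean + 1·SD threshold), RANSAC
   ground-plane segmentation (3 cm tolerance), and a second statistical
   filter of the plant cloud.
2. **Count** — extract the fixed-height band 1.0–1.1 m above the fitted
   plane, Euclidean-cluster it at a 0.10 m tolerance, and classify each
   cluster by the sum of its bounding-box X and Y extents:
   below 0.25 m → bamboo pole, within [0.25, 0.6] m → pseudo-stem,
   above 0.6 m → leaf. The number of stem clusters is the plant count K.
3. **Segment** — split the plant cloud into single plants with K-means on
   the XY projection, K fixed and centroids seeded at the stem cluster
   centroids.
4. **Measure diameter** — per plant, smooth the fixed-height cluster with
   moving least squares and fit a cylinder by RANSAC (surface-normal
   sampling, Gauss–Newton refinement); the diameter is 2r.
5. **Measure height** — estimate the stem axis from the two slabs flanking
   the band, keep points within r + 0.15 m of the axis, scan consecutive
   axial windows of thickness d = 0.05 m and flag a window as leafy when its
   extent sum a + b exceeds 4r + w (w = 0.10 m); the lowest run of flagged
   windows that reaches the top of the cloud marks the leaf/stem junction
   (spurious runs from wilted petioles are skipped by re-entering 3d above
   them). The pseudo-stem height is H = |upper − lower|, the along-axis
   distance from the junction's top point to the lowest near-axis ground
   point; H > 5 m is reported as a failed measurement.
6. **Evaluate** — precision / recall / percentage error for counts, and
   RMSE / MAPE / R² for diameter and height against ground truth.

A parametric synthetic banana-plot generator (`generate_scene()`) produces
labelled scenes with exact per-plant ground truth — stems, drooping leaf
blades, wilted petioles, bamboo poles, broken-leaf patches, rough ground,
range noise and dropout — so every stage of the pipeline is verifiable
without field data.

## Worked example

```r
library(stalkscan)

scene <- generate_scene(scene_spec(seed = 3))       # 3 x 3 plot, 9 plants
res   <- run_pipeline(scene$cloud[, c("x", "y", "z")],
                      pipeline_config(rng_seed = 3))

glance_pipeline(res)
#> # A tibble: 1 × 6
#>       K n_clusters n_pole n_leaf n_measured_ok n_rows
#>   <int>      <int>  <int>  <int>         <int>  <int>
#> 1     9         11      0      2             9     11

res$measurements[1:4, c("plant_id", "band", "diameter_m", "height_m", "status")]
#> # A tibble: 4 × 5
#>   plant_id  band diameter_m height_m status
#>      <int> <int>      <dbl>    <dbl> <chr>
#> 1        1     1     NA        NA    fit_failed
#> 2        1     2      0.242     2.19 ok
#> 3        2     1      0.221     2.12 ok
#> 4        3     1     NA        NA    fit_failed
```

K = 9 is the plant count (this plot also holds two broken leaves, classified
`leaf` and so not counted). Each row is one band cluster of one segmented
plant: the two `fit_failed` rows are broken-leaf fragments that fell into a
plant's segment and, correctly, support no cylinder; the nine `ok` rows are
the pseudo-stems, with diameter and height in metres. Against the
generator's truth the diameters here are within 0.6 mm and the heights
within 4 cm. Per-plant
counting, evaluation against a truth table, and threshold sweeps are exposed
as `count_plants()`, `evaluate_count()` and `run_threshold_sweep()`; results
write to CSV/JSON via `write_plant_csv()` and plot via `plot_cloud()` /
`plot_regression()`.

A thin command-line wrapper lives at `inst/cli/stalkscan`
(`simulate | preprocess | count | run | sweep | convert`).

## Acceptance script

`scripts/acceptance.R` re-runs the whole chain from scratch — it generates
the default synthetic plot for the given seed, executes the full pipeline
(count → segment → measure), logs the counting and measurement summary, and
writes its JSON result to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
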