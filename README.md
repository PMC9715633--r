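# alpinepheno

Tools for analysing the seasonal dynamics of alpine grassland growth and
senescence — above and below ground — in experiments that manipulate the
start of the growing season (e.g. monoliths moved into climate chambers
months before natural snowmelt, compared with field plots).

Alpine plants compress their annual development into a 2–3 month window.
The scientific question this toolchain serves: if the thermal growing
season is made much longer, do plants keep growing — or do they start *and
stop* early, leaving the extra season unused? Answering it requires a
pipeline that turns heterogeneous raw records into comparable per-unit
phenology metrics:

* **Canopy greenness** from RGB photographs: the green chromatic
  coordinate `gcc = G / (R + G + B)` over a region of interest (ratio of
  channel means by default, per-pixel option).
* **Mini-rhizotron scan processing**: removal of vertical scanner stripes
  (FFT notch), brightness/contrast normalization, phase-correlation
  alignment of each scan stack, grid tiling, classical multi-scale ridge
  segmentation of roots (a deterministic stand-in for a trained CNN,
  behind a pluggable parameter object), and quantification of root area
  (mm² cm⁻²) and diameters (medial-axis convention).
* **Phenometrics** per experimental unit: series scaled to percent of
  maximum, penalized-spline smoothers (mgcv GAM, GCV-selected smoothness,
  at most eight knots, evaluated on a daily grid), and the derived
  timepoints — peak date, 50 % decline (linear interpolation on raw
  measurements), growth quantiles (e.g. the day 80 % of seasonal root gain
  is reached), maximum-rate date, and area under the curve
  (daily rectangle rule).
* **Season & temperature**: snowmelt detection from soil-temperature logs
  (first run of days with mean > 3 °C and restored diurnal fluctuations),
  configured meteorological season ends, interval means, growing degree
  hours above 5 °C, pooling of visits < 7 days apart, and
  elongation/browning rates restricted to the paper-style phase windows
  (season start → peak − 14 d; peak + 14 d → 50 % browning + 7 d).
* **Vigour & statistics**: a photosynthetic vigour index
  `max leaf length × (1 + √n_leaves) × (1 − brown fraction) × chlorophyll`,
  pairwise group contrasts from a one-way linear model (pooled SE,
  unadjusted two-sided t), paired max-vs-last percent changes, and simple
  OLS regressions with slope inference.
* **Synthetic data with ground truth**: soil-temperature series with a
  snow-covered ~0 °C phase, logistic rise × decline growth trajectories
  (optional late second greening), cumulative-logistic root gain, canopy
  images with known green fraction, and rhizotron stacks with known masks,
  stripes and shifts — so every stage of the pipeline is testable without
  any downloads.

## Worked example

A full synthetic study mirrors the experimental design: season starts
advanced by ~4 months (day 49, n = 8), ~2 months (day 113, n = 8) and the
natural start (day 183, n = 5), common season end on day 288. Trajectory
shapes are anchored to each group's season start.

```r
library(alpinepheno)
res <- run_pipeline(run_config(seed = 1))

subset(res$summaries, metric == "days_to_peak" & variable == "greenness")
#>   group       metric   mean       se n  variable
#>  plus4m days_to_peak 41.250 1.030776 8 greenness
#>  plus2m days_to_peak 41.625 1.387926 8 greenness
#>   field days_to_peak 39.200 2.059126 5 greenness

subset(res$contrasts, variable == "greenness")
#>            label estimate       se          t df         p  variable
#>   plus2m - field    2.425 2.133813  1.1364630 18 0.2706673 greenness
#>   plus4m - field    2.050 2.133813  0.9607213 18 0.3494211 greenness
#>  plus4m - plus2m   -0.375 1.871478 -0.2003764 18 0.8434328 greenness
```

Canopy greenness peaks ~39–42 days after the start of summer conditions in
*every* group — a 134-day head start does not shift the developmental
programme — and no pairwise days-to-peak contrast is distinguishable from
zero. The 80 % root-growth quantile behaves the same way
(`subset(res$summaries, metric == "q80_doy")`: day 105.0 / 169.3 / 234.5,
i.e. 52–56 days after each group's own season start).

Greenness from a synthetic photograph with known composition:

```r
img <- gen_canopy_image(256, 256, green_fraction = 0.62, jitter_sd = 8,
                        seed = 7)
canopy_greenness(img$image)        # 0.4705
img$truth$expected_greenness       # 0.4706 (closed form)
```

## Command line

```sh
exec/alpinepheno synth --out study/ --seed 1          # synthetic study CSVs
exec/alpinepheno run --config cfg.yaml --out results/ # full pipeline
exec/alpinepheno greenness photo.png --roi mask.png
```

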