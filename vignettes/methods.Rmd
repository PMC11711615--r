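---
title: "Methods: climate classification, model ranking, and consensus mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: climate classification, model ranking, and consensus mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(climclass)
```

## Overview

`climclass` implements a complete map-production chain for model-based
global climate classification:

1. derive classification inputs from gridded monthly temperature and
   precipitation climatologies;
2. classify every grid box under four classification systems (Köppen,
   Holdridge life zones, Thornthwaite–Feddema, Whittaker–Ricklefs biomes);
3. score an ensemble of climate models against a reference with
   area-weighted skill metrics, and select a top-10 sub-ensemble;
4. quantify per-pixel uncertainty with two consensus metrics (percent
   confidence and inter-model class agreement);
5. export the products as NetCDF, GeoTIFF, and BIL rasters.

A synthetic climate-ensemble generator stands in for real model output so
the whole chain runs self-contained. This vignette documents the exact
rules, formulas, and numerical conventions.

## Input climatologies

A `monthly_climatology()` holds 12-month mean temperature (°C) and monthly
precipitation totals (mm) on a regular latitude–longitude grid, with a
land mask. `derive_climatology()` computes the per-pixel statistics the
classifiers need: annual totals and extremes, and the precipitation
falling in each *half-year*. Summer is April–September in the northern
hemisphere and October–March in the southern (pixels at latitude ≥ 0 use
the northern convention). All area weighting uses the cosine of latitude,
normalized over unmasked cells.

## The four classification systems

### Köppen (11 classes)

The reduced Köppen scheme distinguishes 11 classes: Af, Aw, BS, BW, Cs,
Cw, Cf, Dw, Df, ET, EF. Aridity is decided *first*. The annual aridity
threshold (mm·yr⁻¹) depends on the seasonal concentration of
precipitation:

* winter half-year holds ≥ 70% of precipitation: `2·T_avg`
* summer half-year holds ≥ 70%: `2·T_avg + 28`
* otherwise: `2·T_avg + 14`

If annual precipitation is at or below the threshold, the pixel is desert
(BW, below half the threshold) or steppe (BS). Otherwise thermal types
apply: tropical (coldest month ≥ 18 °C; Af when the driest month has
≥ 60 mm, else Aw), temperate (coldest month in [−3, 18) °C; Cs when the
wettest winter month has at least 3× the driest summer month, Cw when the
wettest summer month has at least 10× the driest winter month, else Cf),
continental (coldest month < −3 °C and warmest > 10 °C; Dw by the same
10× summer rule, else Df), and polar (warmest month ≤ 10 °C; ET when the
warmest month is at or above 0 °C, else EF). We close the polar boundary
at exactly 10 °C so that the cascade is exhaustive.

### Holdridge life zones (33 zones, 13 biome groups)

Each pixel is described by three variables:

* annual **biotemperature** `ABT`: the mean of monthly temperatures after
  clamping each month into [0, 30] °C;
* annual precipitation `APP` (mm);
* the potential-evapotranspiration ratio `PER = 58.93 · ABT / APP`.

Classification is nearest-centroid among 33 published life-zone centroids
in log₂ space (the Holdridge chart's axes are geometric: precipitation
levels double row to row). Values are floored before taking logarithms
(`APP` at 1 mm; `ABT` and `PER` at 2⁻⁶) so cold or wet extremes stay
finite. Exact ties resolve to the earlier table row. The 33 zones
aggregate into 13 biome groups for mapping.

### Thornthwaite–Feddema (36 types)

The classic Thornthwaite potential evapotranspiration: with heat index
`I = Σ (T/5)^1.514` over months with `T > 0` and exponent
`a = 6.75e-7·I³ − 7.71e-5·I² + 1.792e-2·I + 0.49239`, the monthly
unadjusted PET is `16·(10·T/I)^a` mm, replaced above 26.5 °C by the
quadratic `−415.85 + 32.24·T − 0.43·T²`. Each month is scaled by
`(L/12)·(days/30)` where `L` is day length from the standard solar
declination formula. The Feddema moisture index compares annual
precipitation `r` with annual PET `PE`:

* `Im = r/PE − 1` when `r < PE` (negative, dry side)
* `Im = 1 − PE/r` otherwise (positive, wet side)

so `Im` is antisymmetric and bounded in (−1, 1], with supremum 1. The
classification crosses six thermal bands (PE breaks at 300, 600, 900,
1200, 1500 mm; Frigid→Torrid) with six moisture bands (Im breaks at
−0.66, −0.33, 0, 0.33, 0.66; Arid→Saturated), all lower-inclusive, for
36 types. Pixels with `r = PE = 0` take `Im = 0` and are counted as
undefined.

### Whittaker–Ricklefs biomes (9 biomes)

Nine biome polygons partition the plane of mean annual temperature (°C)
versus annual precipitation (cm). Membership is point-in-polygon by
even-odd ray casting, with on-edge points counting as inside and shared
edges resolved by file order. Points outside every polygon (physically
plausible but off-chart climates) are assigned to the nearest polygon
edge, with the two axes scaled by the chart ranges (70 °C, 450 cm) so
distance is unit-free. The polygon vertex table bundled with the package
is a synthetic digitization that tiles the climate envelope with simple
polygons; it preserves the structure (9 biomes, shared boundaries), not
the exact published curves.

## Model ranking and the top-10 ensemble

Each ensemble member is scored against the reference with:

* area-weighted Cohen's kappa `κ = (P₀ − P_e)/(1 − P_e)` of its class map
  for the chosen scheme, where `P₀` is the area-weighted agreement and
  `P_e` the chance agreement from the two maps' class frequencies;
* area-weighted `R²` of annual precipitation and of annual mean
  temperature. The default form is the skill score
  `1 − Σw(m−o)² / Σw(o−ō)²`, which penalizes bias; the squared weighted
  Pearson correlation is available as an option.

Selection takes the upper-right quadrant of the (κ, precipitation-R²)
plane — both metrics at or above the cohort medians, inclusive — and
keeps the 10 highest-κ members of that quadrant. The selected members are
averaged month-by-month (`ensemble_mean()`) and the mean climatology is
classified to give the top-10 ensemble map.

## Consensus products

Uncertainty is summarized per pixel from the selected members' class
votes against the reference map:

* **Confidence** `= 100 · coincident members / N members`, discretized
  into five categories: very high (≥ 80%), high (60–79%), moderate
  (40–59%), low (20–39%), very low (< 20%).
* **Inter-model class agreement** (`modvar`): the count of distinct
  classes the members assign to the pixel; three or more distinct classes
  flags high inter-model variability.

`build_consensus_product()` bundles both with the grid and legend;
`export_consensus()` writes the category and count layers as 8-bit
rasters and the continuous confidence field to NetCDF.

## The synthetic generator

`make_reference()` builds an Earth-like reference climate: a zonal
temperature profile warm at the equator and far below freezing at the
poles, seasonal amplitude growing poleward with opposite phase in the two
hemispheres, a tropical precipitation peak with subtropical dry belts and
mid-latitude storm tracks, multiplicative lognormal spatial texture,
regionally varying wet-summer versus wet-winter seasonality, and
pseudo-continents from a thresholded smooth random field (default land
fraction 0.35, south-polar cap excluded). `make_ensemble()` perturbs the
reference per member with smooth spatially correlated bias fields plus
white pixel noise — additive for temperature, multiplicative lognormal
for precipitation — and a per-member skill multiplier drawn from
`skill_spread` so the cohort genuinely varies in quality.
`apply_scenario()` adds polar-amplified warming and subtropical drying
for future-scenario runs. Defaults (52 members, 1° resolution) match the
study design; everything is deterministic in `seed` and leaves the
caller's RNG state untouched.

The generator is a *test harness*, not a climate model: it has no
orography, ocean circulation, or interannual variability, and its
continents are random. Its purpose is to exercise every classifier branch
(at 1° it produces at least 8 Köppen, 9 Holdridge, 20 Feddema, and 7
Whittaker classes) and to give the ranking and consensus stages an
ensemble with a known truth.

## A small worked run

A reduced-size run (coarse grid, 12 members) keeps the vignette light;
study-scale runs simply change the configuration.

```{r pipeline, eval = FALSE}
cfg <- synthetic_config(seed = 1, n_members = 12, res = 4)
res <- run_pipeline(cfg, outdir = tempfile("run"), schemes = "whittaker")
res$scorecards$whittaker
print(res$consensus$whittaker)
```

## Numerical conventions

* Köppen aridity thresholds are in mm·yr⁻¹ and may be non-positive for
  very cold climates (then the arid branch simply never triggers).
* Holdridge distances use log₂ coordinates with the floors given above;
  tie-breaks go to the earlier table row.
* All band classifications (Feddema thermal/moisture, confidence
  categories) are lower-inclusive, and the Köppen 70% seasonal
  concentration tests are inclusive.
* File formats are written from first principles: NetCDF-3 classic
  (big-endian, 4-byte aligned), single-strip uncompressed 8-bit GeoTIFF
  with GeoTIFF georeferencing tags (WGS84), and BIL with an ASCII header.
  Class codes use nodata 0 in the integer formats.
* Test problem sizes (coarse grids, small ensembles) are the package's
  own choice for fast feedback; defaults of `synthetic_config()` are the
  study-scale conditions.
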