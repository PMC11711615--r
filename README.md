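# climclass

Global climate classification, model ranking, and per-pixel consensus
(uncertainty) mapping for gridded monthly climatologies.

## The problem

Climate classification systems compress monthly temperature and
precipitation into a discrete map of climate types. When the inputs come
from an *ensemble* of climate models rather than observations, two
questions follow: which models reproduce the observed class map best, and
where on the map do the models disagree? `climclass` implements the full
chain that answers both:

1. **Classification.** Four systems applied per grid box:
   - **Köppen** (reduced, 11 classes — Af, Aw, BS, BW, Cs, Cw, Cf, Dw,
     Df, ET, EF), aridity decided first from the threshold
     `2·T_avg (+ 0 / 14 / 28)` mm·yr⁻¹ depending on whether precipitation
     concentrates in the winter half-year, neither, or the summer
     half-year;
   - **Holdridge life zones** (33 zones, 13 biome groups),
     nearest-centroid in the log₂ chart of annual biotemperature
     (monthly temperatures clamped to [0, 30] °C before averaging),
     annual precipitation, and the ratio `PER = 58.93·ABT/APP`;
   - **Thornthwaite–Feddema** (36 types), crossing annual Thornthwaite
     potential evapotranspiration `PE` with the moisture index
     `Im = r/PE − 1` (dry side) or `1 − PE/r` (wet side);
   - **Whittaker–Ricklefs biomes** (9), point-in-polygon in the plane of
     mean annual temperature vs. annual precipitation, nearest-edge for
     off-chart climates.
2. **Ranking.** Area-weighted Cohen's kappa of each member's class map
   against the reference map, plus area-weighted R² for annual
   precipitation and temperature; the **top-10 ensemble** is the 10
   highest-κ members of the upper-right median quadrant of the
   (κ, precipitation-R²) plane.
3. **Consensus.** Per pixel, from the selected members' class votes:
   percent **confidence** (`100 · coincident/N`, binned ≥80 / 60–79 /
   40–59 / 20–39 / <20) and **inter-model class agreement** (count of
   distinct classes; ≥3 flags high variability).
4. **Export.** NetCDF-3, GeoTIFF, and BIL rasters under the
   `scheme_variable_scenario_period.ext` naming convention, written from
   first principles (no external raster libraries).

A synthetic climate-ensemble generator (`synthetic_config()`,
`make_reference()`, `make_ensemble()`) provides an Earth-like reference
and a perturbed model cohort with known truth, so the entire pipeline
runs with no external data. See the methods vignette
(`vignettes/methods.Rmd`) for the precise rules and numerical
conventions.

## Worked example

```r
library(climclass)
cfg <- synthetic_config(seed = 1, n_members = 12, res = 4)
res <- run_pipeline(cfg, schemes = "whittaker")

print(res$ref_maps$whittaker)
#> <class_map> scheme whittaker (class), 45 x 90, 1261 classified cells
#>   9/9 legend classes present; scenario historical, period 1980-2014

cards <- res$scorecards$whittaker
head(cards[order(cards$rank),
           c("model", "kappa", "r2_pr", "r2_ts", "selected")], 5)
#>     model kappa r2_pr r2_ts selected
#>  model_03 0.925 0.981 0.998     TRUE
#>  model_10 0.893 0.963 0.998     TRUE
#>  model_06 0.885 0.925 0.996     TRUE
#>  model_04 0.876 0.913 0.995    FALSE
#>  model_02 0.865 0.973 0.995     TRUE

print(res$consensus$whittaker)
#> <consensus_product> scheme whittaker, 4 members, 45 x 90
#>   mean confidence 91.9%; high-variability area: 0.9% of pixels
#>   reference: whittaker historical 1980-2014
```

(`model_04` has the fourth-best κ but falls below the cohort's median
precipitation-R², so the median-quadrant screen drops it.) Passing
`outdir =` additionally writes the class maps, consensus layers,
per-scheme scorecards, and a JSON run manifest. Study-scale runs use the
defaults — 52 members at 1° — via `run_pipeline(synthetic_config(seed),
outdir = "...")`.

The same chain is available from the command line:

```sh
Rscript inst/cli/climclass export --seed 1 --outdir out --scheme whittaker
```

## Package layout

- `R/grids.R` — climatology container, derived statistics, area weights,
  bilinear regridding
- `R/koppen.R`, `R/holdridge.R`, `R/thornthwaite.R`, `R/whittaker.R` —
  the four classifiers (`classify_map_*()` for gridded use)
- `R/evaluation.R` — kappa, weighted R², scorecards, top-10 selection,
  ensemble mean
- `R/consensus.R` — confidence, class-agreement counts, consensus product
- `R/synthetic.R` — reference generator, ensemble perturbation, scenario
  forcing
- `R/io_*.R`, `R/pipeline.R` — NetCDF/GeoTIFF/BIL writers and readers,
  product export, orchestration
- `inst/cli/climclass` — command-line front end
  (`simulate`/`classify`/`rank`/`consensus`/`export`)
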