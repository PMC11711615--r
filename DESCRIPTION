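Package: climclass
Title: Global Climate Classification, Model Ranking and Consensus Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Applies four global climate classification systems (Koeppen,
    Holdridge life zones, the Feddema revision of Thornthwaite, and
    Whittaker-Ricklefs biomes) to gridded monthly temperature and
    precipitation climatologies on a regular latitude-longitude grid.
    Ranks climate-model ensemble members against a reference with
    area-weighted Cohen's kappa and coefficient-of-determination skill
    scores, selects a top-10 ensemble by median-quadrant screening, and
    builds per-pixel consensus products (percent confidence against a
    reference map and inter-model class-agreement counts). Includes a
    synthetic climate-ensemble generator so the full pipeline runs with
    no external data, plus raster export to NetCDF, GeoTIFF and BIL.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    mgcv,
    pracma,
    rmarkdown,
    testthat (>= 3.0.0),
    tiff
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
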