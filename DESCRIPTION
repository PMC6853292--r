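Package: cycloidSV
Title: Cycloid-Grid Stereology for Serial-Section Electron Microscopy Segmentations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Vertical-section stereology for segmented serial block-face
    scanning electron microscopy (SBF-SEM) label stacks. Implements cycloid
    test grids with restriction-line bookkeeping, the classical
    surface-to-volume estimator 2*sum(I) / ((l/p) * sum(P)) from line
    intersections and point counts, Cavalieri-style volume extraction from
    voxel labels, basal-lamina pore diameter measurement (maximum Feret
    diameter), nerve-bundle phenotype classification by pore connectivity,
    and the accompanying group statistics (pooled two-tailed t test,
    exact Mann-Whitney U). A synthetic phantom generator produces labeled
    stacks of nerve bundles with closed-form surface area and volume, so
    every estimator can be validated against analytic ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'phantom-shapes.R'
    'scene.R'
    'voxelize.R'
    'grid.R'
    'count.R'
    'estimators.R'
    'cohort.R'
    'cycloidSV-package.R'
    'io.R'
    'stats.R'
    'pipeline.R'
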