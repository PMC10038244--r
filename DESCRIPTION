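Package: treatzones
Title: Treatment-Zone Mapping for Emergency Mosquito Control
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Converts county-level vector GIS layers (protected lands,
    hydrology, wetlands, address points, census blocks) into a classified
    one-square-mile treatment-zone grid (Approved / Warning / Not
    Significant) for planning ground and aerial mosquito control after
    flooding events. Implements the full 18-step overlay protocol
    (attribute selection, stream buffering, merge/clip/dissolve of
    biologically sensitive areas, address-indexed fishnet gridding, erase,
    distance-based warning classification, wetland-based approval, and
    area-weighted census population apportionment), per-class area and
    population summaries, and cost projection from vetted acres. Includes
    a seeded synthetic-county generator and an independent rasterized
    classification oracle for validation, plus readers and writers for
    Shapefile, GeoJSON and GeoPackage with a built-in State Plane
    (Lambert conformal conic) projection engine.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    polyclip,
    sp,
    jsonlite,
    yaml,
    foreign,
    tools,
    utils,
    stats,
    grDevices,
    graphics,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'geom-core.R'
    'crs.R'
    'AllClasses.R'
    'io-geojson.R'
    'io-shapefile.R'
    'io-gpkg.R'
    'gis-io.R'
    'pipeline-ops.R'
    'pipeline-run.R'
    'synthetic.R'
    'oracle.R'
    'cli.R'
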