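# treatzones

Classified treatment-zone grids for emergency mosquito control.

After hurricane flooding, county public-health authorities and mosquito
control programs need pre-approved maps showing where insecticide can be
applied, where protected land rules it out, and where treatment would be
wasted. `treatzones` implements the full 18-step GIS overlay protocol that
turns a county's standard vector layers — protected lands (GAP status /
owner type), stream and river centerlines, water bodies, wetlands, address
points, and census blocks — into a classified 1 mi² fishnet grid:

| class | meaning |
|---|---|
| **Approved** | treatable; intersects wetlands (mosquito habitat) |
| **Warning** | treatable; within 100 ft of the buffered sensitive area (drift caution) |
| **Not Significant** | populated but no wetland habitat; not treated |

Formally, with county polygon `C`, filtered heritage polygons `H`
(`GAP ∈ {1,2}` or federal owner), streams `S`, water bodies `W` and
wetlands `M`:

```
sensitive  = dissolve( buffer( clip(W ∪ buffer(S, 50 ft) ∪ H, C), 100 ft ) )
grid       = fishnet(1 mi² cells indexed to address points)
cells      = grid ⊖ sensitive                      (erase; drop slivers)
Warning    = { c ∈ cells : dist(c, sensitive) ≤ 100 ft }
Approved   = { c ∈ cells ∖ Warning : c intersects clip(M, C) }
NotSignif. = the rest
pop(c)     = Σ_b pop(b) · area(c ∩ b) / area(b)    (area-weighted blocks)
```

Per-class areas are reported in mi² (2 dp) and acres (mi² × 640); the
vetted (Approved + Warning) acres drive cost and product projections.
All distances are interpreted in the working CRS's linear unit; the default
working CRS is EPSG:2264 (NC State Plane, US survey foot). The package also
ships a seeded synthetic-county generator and an independent rasterized
classification oracle (scanline fill + distance transforms) used to
cross-validate the vector pipeline.

## Worked example

```r
library(treatzones)

params <- countyParams(seed = 1)          # 10-mile synthetic county
layers <- generateCounty(params)
config <- pipelineConfig()                # 50 ft / 100 ft / 100 ft / 1 mi^2
res <- runPipeline(layers, config)
res$summary
#> ZoneSummary
#>             type cell_count   area_ft2 area_mi2 area_acres population
#>         Approved         24  669081600    24.00    15360.0  1866.3895
#>          Warning         27  626224516    22.46    14374.4  2173.5109
#>  Not Significant         14  390297600    14.00     8960.0   494.8807
#>            Total         65 1685603716    60.46    38694.4  4534.7811

estimateTreatmentCost(res$summary, costPerAcre = 1.5, productRate = 0.8)
#>   treatable_acres    cost product
#> 1         29734.4 44601.6 23787.52
```

65 of the county's address-bearing cells survive the erase step; 24 mi² are
Approved wetland habitat, 22.46 mi² are treatable but flagged Warning near
protected land, and treating the 29 734 vetted acres at $1.50/acre would
cost $44 602 and use 23 788 oz of product at 0.8 oz/acre. The independent
10-ft raster oracle reproduces each class area to well under 1%:

```r
referenceAreas(rasterOracle(layers, config, 10)) / 27878400
#>        Approved         Warning Not Significant
#>        24.00000        22.46869        14.00000
```

File-based runs use `cmdRun()` (or the `inst/cli/treatzone` script), which
reads Shapefile/GeoJSON/GeoPackage layers, reprojects and repairs them,
runs the protocol, and writes `classified_grid.geojson`,
`zone_summary.csv`, `manifest.json` and an optional `map.png`:

```sh
inst/cli/treatzone run \
  --county-layer county.gpkg --heritage-layer nhp.gpkg \
  --streams-layer streams.gpkg --waterbodies-layer lakes.gpkg \
  --wetlands-layer wetlands.gpkg --addresses-layer addresses.gpkg \
  --blocks-layer blocks2020.gpkg --county Brunswick --out out/
```

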