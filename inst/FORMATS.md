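# Artifact formats

All coordinates are planar meters.  CSV files are comma-separated with a
header row and no quoting.

## tubes.csv
One row per sampling tube and survey wave.

| column  | meaning                                   |
|---------|-------------------------------------------|
| tube_id | tube identifier, shared across waves      |
| x, y    | tube location (m)                         |
| period  | `wave1` or `wave2`                        |
| scale   | severity 0-3 (0 none, 1 = 1-4 ants, 2 = 5-49, 3 = >= 50) |

## cells.csv
Per-cell state of the 200 m surveillance grid (`i` = row, `j` = column,
zero-based from the grid origin).

| column         | meaning                                    |
|----------------|--------------------------------------------|
| i, j           | cell index                                 |
| max_s1, max_s2 | per-wave maximum severity (empty if unsampled) |
| label          | `SIRH`, `USIRL` or `undefined`             |

## labelled_tubes.csv
Wave-2 tubes with the inherited cell label: `tube_id,x,y_coord,period,scale,y`
(`y` = 1 for SIRH; `y_coord` is the planar y coordinate).

## model_table.csv
Model rows: `tube_id,y,landuse5,road_dist,x,y_coord`.  `landuse5` is one of
natural, artificial, transportation, agriculture, change; `road_dist` is the
nearest-road distance (m).

## risk_surface.csv
`i,j,x_center,y_center,p,lp_landuse,lp_dist,lp_spatial`: probability and the
three linear-predictor components at each cell center (components sum to the
total linear predictor).

## GeoJSON layers
`landuseA.geojson` / `landuseB.geojson`: FeatureCollections of Polygons with
a `category` property.  `roads.geojson`: LineString features.  A `crs_note`
property records that coordinates are planar meters.

## Fit and report JSON
`fit_<model>.json`: coefficients, odds-ratio table, smooth-term tests, EDFs,
AIC, smoothing parameters, convergence.  `comparison.json`: AIC table,
analysis-of-deviance rows, selected model.  `report.json`: severity
distributions, contingency table with Pearson chi-square, distance
thresholds.
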