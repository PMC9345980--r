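# Plain-text artifact I/O: tube/cell/model-table CSV and GeoJSON layers.
# Column layouts are documented in inst/FORMATS.md.

#' Write / read sampling-tube tables
#'
#' Tube CSV carries `tube_id,x,y,period,scale`; `scale` may be empty before
#' simulation.  Reading validates the schema and severity range and names the
#' offending row on failure.
#'
#' @param tubes tube data frame.
#' @param path file path.
#' @return `read_tubes_csv` returns the validated data frame.
#' @export
write_tubes_csv <- function(tubes, path) {
  utils::write.csv(tubes[, c("tube_id", "x", "y", "period", "scale")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tubes_csv
#' @export
read_tubes_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("tube_id", "x", "y", "period", "scale")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_fmt("%s: missing columns: %s", path, paste(miss, collapse = ", "))
  bad <- which(!(is.na(df$scale) | df$scale %in% 0:3))
  if (length(bad))
    stop_fmt("%s: invalid severity scale %s in row %d (tube %s)",
             path, df$scale[bad[1]], bad[1], df$tube_id[bad[1]])
  if (any(!is.finite(df$x)) || any(!is.finite(df$y)))
    stop_fmt("%s: non-finite coordinates", path)
  df
}

#' @rdname write_tubes_csv
#' @param cells per-cell state table from [cell_states()].
#' @export
write_cells_csv <- function(cells, path) {
  utils::write.csv(cells[, c("i", "j", "max_s1", "max_s2", "label")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tubes_csv
#' @export
read_cells_csv <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)

#' @rdname write_tubes_csv
#' @param table model-row table from [attach_covariates()].
#' @export
write_model_table_csv <- function(table, path) {
  utils::write.csv(table[, c("tube_id", "y", "landuse5", "road_dist", "x", "y_coord")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tubes_csv
#' @export
read_model_table_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("tube_id", "y", "landuse5", "road_dist", "x", "y_coord")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_fmt("%s: missing columns: %s", path, paste(miss, collapse = ", "))
  if (!all(df$y %in% 0:1)) stop_fmt("%s: response y must be 0/1", path)
  if (!all(df$landuse5 %in% LU5))
    stop_fmt("%s: unknown land-use category '%s'",
             path, setdiff(df$landuse5, LU5)[1])
  df$landuse5 <- landuse5_factor(df$landuse5)
  df
}

# rings for a rectangle-backed layer
layer_rings <- function(layer) {
  if (!is.null(layer$rings)) return(layer$rings)
  lapply(seq_len(nrow(layer$rects)), function(k) {
    r <- layer$rects[k, ]
    rect_ring(r$xmin, r$xmax, r$ymin, r$ymax)
  })
}

#' Write / read land-use layers and road networks as GeoJSON
#'
#' Layers are FeatureCollections of Polygons carrying a `category` property;
#' roads are LineString features.  Coordinates are planar meters (no CRS
#' transformation is performed; the `crs_note` property records this).
#'
#' @param layer a `landuse_layer`.
#' @param path file path.
#' @export
write_landuse_geojson <- function(layer, path) {
  rings <- layer_rings(layer)
  feats <- lapply(seq_along(rings), function(k) {
    ring <- rings[[k]]
    if (any(ring[1, ] != ring[nrow(ring), ]))
      ring <- rbind(ring, ring[1, ])
    list(type = "Feature",
         properties = list(category = layer$category[k]),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) ring[i, ]))))
  })
  obj <- list(type = "FeatureCollection",
              properties = list(crs_note = "planar meters"),
              features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_landuse_geojson
#' @export
read_landuse_geojson <- function(path) {
  obj <- jsonlite::read_json(path)
  if (!identical(obj$type, "FeatureCollection"))
    stop_fmt("%s: not a GeoJSON FeatureCollection", path)
  cats <- character(0); rings <- list()
  for (f in obj$features) {
    if (!identical(f$geometry$type, "Polygon")) next
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(p) c(p[[1]], p[[2]])))
    cats <- c(cats, f$properties$category)
    rings[[length(rings) + 1L]] <- ring
  }
  if (!all(cats %in% LU4))
    stop_fmt("%s: unknown land-use category '%s'", path, setdiff(cats, LU4)[1])
  structure(list(category = cats, rings = rings), class = "landuse_layer")
}

#' @rdname write_landuse_geojson
#' @param roads road segment data frame (`x1, y1, x2, y2`).
#' @export
write_roads_geojson <- function(roads, path) {
  feats <- lapply(seq_len(nrow(roads)), function(k) {
    list(type = "Feature", properties = list(road_id = k),
         geometry = list(type = "LineString",
                         coordinates = list(c(roads$x1[k], roads$y1[k]),
                                            c(roads$x2[k], roads$y2[k]))))
  })
  obj <- list(type = "FeatureCollection",
              properties = list(crs_note = "planar meters"),
              features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_landuse_geojson
#' @export
read_roads_geojson <- function(path) {
  obj <- jsonlite::read_json(path)
  segs <- list()
  for (f in obj$features) {
    if (!identical(f$geometry$type, "LineString")) next
    cc <- do.call(rbind, lapply(f$geometry$coordinates,
                                function(p) c(p[[1]], p[[2]])))
    for (k in seq_len(nrow(cc) - 1L))
      segs[[length(segs) + 1L]] <- c(cc[k, ], cc[k + 1L, ])
  }
  if (!length(segs)) stop_fmt("%s: no LineString features", path)
  out <- as.data.frame(do.call(rbind, segs))
  names(out) <- c("x1", "y1", "x2", "y2")
  out
}

#' Serialize a model fit summary as JSON
#'
#' Writes coefficients, the odds-ratio table, smooth-term tests, EDFs, AIC,
#' smoothing parameters and convergence information; alongside, a plain-text
#' report table.
#'
#' @param fit a [pslogit()] / [build_model()] fit.
#' @param path JSON path (`.txt` report written next to it).
#' @export
write_fit_json <- function(fit, path) {
  sm <- summary(fit)
  obj <- list(model = fit$model_name %||% "pslogit",
              n = fit$nobs,
              coefficients = as.list(fit$coefficients),
              parametric = sm$parametric,
              smooth = sm$smooth,
              edf_by_term = as.list(fit$edf_by_block),
              edf_total = fit$edf_total,
              deviance = fit$deviance,
              aic = fit$aic,
              lambda = fit$lambda,
              gcv = fit$gcv,
              converged = fit$converged,
              iterations = fit$iter)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  txt <- sub("\\.json$", ".txt", path)
  writeLines(utils::capture.output(print(sm)), txt)
  invisible(path)
}
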