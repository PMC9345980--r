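# Covariate construction: the five-category land-use-change variable and the
# nearest-road distance attached to every labelled sampling tube.

# Priority used to resolve points lying exactly on a shared polygon boundary
# (measure-zero, but the overlay must be deterministic).
CATEGORY_PRIORITY <- c("transportation", "artificial", "agriculture", "natural")

#' Land-use category at points
#'
#' Returns the category of the polygon containing each point.  A point on a
#' shared boundary resolves by the fixed priority
#' transportation > artificial > agriculture > natural.
#'
#' @param x,y point coordinates (meters).
#' @param layer a `landuse_layer` (from [generate_landscape()] or
#'   [read_landuse_geojson()]).
#' @return character vector of categories.
#' @export
category_at_point <- function(x, y, layer) {
  stopifnot(inherits(layer, "landuse_layer"), length(x) == length(y))
  pr <- match(layer$category, CATEGORY_PRIORITY)  # 1 = highest
  if (!is.null(layer$catmat)) {
    xc <- layer$xcuts; yc <- layer$ycuts
    out_of <- x < xc[1] | x > xc[length(xc)] | y < yc[1] | y > yc[length(yc)]
    if (any(out_of)) {
      b <- which(out_of)[1]
      stop_fmt("point (%g, %g) is not covered by the land-use layer", x[b], y[b])
    }
    ix <- pmin(findInterval(x, xc), length(xc) - 1L)
    iy <- pmin(findInterval(y, yc), length(yc) - 1L)
    out <- layer$catmat[cbind(iy, ix)]
    # points exactly on an interior cut line touch 2 (or 4) cells: resolve by
    # category priority among the touched cells
    onx <- x == xc[ix] & ix > 1L
    ony <- y == yc[iy] & iy > 1L
    for (b in which(onx | ony)) {
      cand_x <- unique(c(ix[b], if (onx[b]) ix[b] - 1L))
      cand_y <- unique(c(iy[b], if (ony[b]) iy[b] - 1L))
      cats <- layer$catmat[as.matrix(expand.grid(cand_y, cand_x))]
      out[b] <- CATEGORY_PRIORITY[min(match(cats, CATEGORY_PRIORITY))]
    }
    return(out)
  }
  # generic polygon layer: ray casting with bounding-box prefilter
  best <- rep(NA_integer_, length(x))
  for (p in seq_along(layer$rings)) {
    ring <- layer$rings[[p]]
    cand <- which(x >= min(ring[, 1]) & x <= max(ring[, 1]) &
                  y >= min(ring[, 2]) & y <= max(ring[, 2]))
    cand <- cand[is.na(best[cand]) | pr[p] < best[cand]]
    if (!length(cand)) next
    hit <- cand[point_in_ring(x[cand], y[cand], ring)]
    best[hit] <- pmin(best[hit], pr[p], na.rm = TRUE)
  }
  if (anyNA(best)) {
    b <- which(is.na(best))[1]
    stop_fmt("point (%g, %g) is not covered by the land-use layer (coverage violation)",
             x[b], y[b])
  }
  CATEGORY_PRIORITY[best]
}

#' Five-category land-use-change variable at points
#'
#' Overlays both reference-year layers: points whose category differs between
#' years are `"change"`; otherwise the (common) category is returned.
#'
#' @param x,y point coordinates (meters).
#' @param layerA,layerB land-use layers for the two reference years.
#' @return factor with levels natural, artificial, transportation,
#'   agriculture, change (natural first: the model reference).
#' @export
landuse5 <- function(x, y, layerA, layerB) {
  a <- category_at_point(x, y, layerA)
  b <- category_at_point(x, y, layerB)
  landuse5_factor(ifelse(a == b, a, "change"))
}

#' Attach model covariates to labelled tubes
#'
#' Builds the model-row table: one row per labelled wave-2 tube with the
#' five-category land-use-change covariate and the nearest-road distance.
#' Logs category frequencies and per-category median road distances.
#'
#' @param labelled_tubes output of [label_tubes()]: columns `tube_id`, `x`,
#'   `y_coord` and binary response `y`.
#' @param bundle a landscape bundle (layers + roads).
#' @param quiet suppress the summary message.
#' @return model-row data frame `tube_id, y, landuse5, road_dist, x, y_coord`.
#' @export
attach_covariates <- function(labelled_tubes, bundle, quiet = FALSE) {
  stopifnot(inherits(bundle, "landscape_bundle"))
  if (is.null(labelled_tubes$y) || is.null(labelled_tubes$y_coord))
    stop_fmt("tubes must be labelled (response y, coordinate y_coord) before covariate attachment")
  xx <- labelled_tubes$x
  yy <- labelled_tubes$y_coord
  lu <- landuse5(xx, yy, bundle$landuseA, bundle$landuseB)
  rd <- nearest_road_distance(xx, yy, bundle$roads)
  if (any(!is.finite(rd))) {
    b <- which(!is.finite(rd))[1]
    stop_fmt("non-finite road distance for tube %s", labelled_tubes$tube_id[b])
  }
  out <- data.frame(tube_id = labelled_tubes$tube_id,
                    y = labelled_tubes$y,
                    landuse5 = lu,
                    road_dist = rd,
                    x = xx,
                    y_coord = yy)
  if (!quiet) {
    med <- tapply(out$road_dist, out$landuse5, stats::median)
    message("attach_covariates: ", nrow(out), " rows; category counts: ",
            paste(names(table(out$landuse5)), as.integer(table(out$landuse5)),
                  sep = "=", collapse = ", "),
            "; median road distance (m): ",
            paste(names(med), round_half_up(med, 1), sep = "=", collapse = ", "))
  }
  out
}
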