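# Synthetic landscape and two-wave surveillance generator.
#
# The generator emulates the structure the risk analysis assumes: a planar
# island extent tiled by land-use patches in two reference years (~10% of the
# area changing category between them), a rectangular road lattice whose
# immediate surroundings are transportation land, and sampling tubes placed
# 1-2 per 200 m grid cell in each of two survey waves.  Everything is driven
# by a single named seed so downstream stages are reproducible bit-for-bit.

#' Generate a synthetic land-use / road landscape
#'
#' Builds a paired pair of land-use layers (reference years A and B), a road
#' polyline network, and exact bookkeeping of the changed-area fraction.
#' Patches are an axis-aligned rectangular tiling of the extent; land within
#' `road_halfwidth` of a road centerline is transportation in both years, so
#' road surroundings never change category.
#'
#' @param seed integer seed; identical seeds give byte-identical bundles.
#' @param extent numeric `c(xmin, xmax, ymin, ymax)` in meters.  The default
#'   is an island-sized 11.6 km x 11.4 km rectangle (about 132 km^2).
#' @param n_patches approximate number of land-use patches.
#' @param change_fraction fraction of the extent area whose category differs
#'   between years A and B (in `[0, 1)`).
#' @param road_spacing spacing of the road lattice in meters.
#' @param road_halfwidth half-width of the transportation strip along each
#'   road centerline (meters).
#' @param shares named year-A area shares for the patch categories.
#'   Transportation is deliberately absent from the default: transportation
#'   land is exactly the strip along roads (at the default spacing and
#'   half-width about 5.9% of the extent), which gives transportation tubes a
#'   road distance of 0, as observed in the surveillance data.
#' @param dev_fraction fraction of changed area drawn from natural patches
#'   converted to development (agriculture/transportation/artificial).
#' @return an object of class `landscape_bundle`: list with `extent`,
#'   `landuseA`, `landuseB` (class `landuse_layer`), `roads` (segment data
#'   frame), `crs_note`, `params` and `meta` (achieved change fraction etc.).
#' @export
generate_landscape <- function(seed,
                               extent = c(0, 11600, 0, 11400),
                               n_patches = 400,
                               change_fraction = 0.107,
                               road_spacing = 800,
                               road_halfwidth = 12,
                               shares = c(natural = 0.522, artificial = 0.104,
                                          agriculture = 0.211),
                               dev_fraction = 0.616) {
  stopifnot(length(extent) == 4)
  W <- extent[2] - extent[1]; H <- extent[4] - extent[3]
  if (W <= 0 || H <= 0)
    stop_fmt("degenerate extent (zero area): [%g, %g] x [%g, %g]",
             extent[1], extent[2], extent[3], extent[4])
  check_number(change_fraction, "change_fraction", 0, 1 - 1e-12)
  check_number(road_spacing, "road_spacing", lower = 1e-9)
  if (is.null(names(shares)) || !all(names(shares) %in% LU4))
    stop_fmt("'shares' must be named with the four base land-use categories")
  shares <- shares / sum(shares)

  with_seed(seed, {
    nc <- max(1L, round(sqrt(n_patches * W / H)))
    nr <- max(1L, round(n_patches / nc))
    xb <- seq(extent[1], extent[2], length.out = nc + 1)
    yb <- seq(extent[3], extent[4], length.out = nr + 1)
    np <- nr * nc
    catA <- sample(names(shares), np, replace = TRUE, prob = shares)

    # road lattice, offset from the extent edge so centerlines sit in the
    # interior of 200 m surveillance cells rather than on their boundaries
    off <- road_spacing / 8
    vx <- seq(extent[1] + off, extent[2], by = road_spacing)
    hy <- seq(extent[3] + off, extent[4], by = road_spacing)
    roads <- rbind(
      data.frame(x1 = vx, y1 = extent[3], x2 = vx, y2 = extent[4]),
      data.frame(x1 = extent[1], y1 = hy, x2 = extent[2], y2 = hy)
    )
    strip_x <- cbind(pmax(vx - road_halfwidth, extent[1]),
                     pmin(vx + road_halfwidth, extent[2]))
    strip_y <- cbind(pmax(hy - road_halfwidth, extent[3]),
                     pmin(hy + road_halfwidth, extent[4]))

    # free (non-strip) area of each patch: strips are full-extent bands, so
    # the free region of a patch is a product of 1-D complements
    free_len <- function(a, b, ints) {
      tot <- b - a
      if (nrow(ints)) {
        lo <- pmax(ints[, 1], a); hi <- pmin(ints[, 2], b)
        tot <- tot - sum(pmax(hi - lo, 0))
      }
      tot
    }
    px <- rep(seq_len(nc), each = nr)   # patch column
    py <- rep(seq_len(nr), times = nc)  # patch row
    fx <- vapply(seq_len(nc), function(j) free_len(xb[j], xb[j + 1], strip_x), 0)
    fy <- vapply(seq_len(nr), function(i) free_len(yb[i], yb[i + 1], strip_y), 0)
    free_area <- fx[px] * fy[py]
    total_area <- W * H

    # pick patches to change so the changed (free) area hits the target,
    # drawing dev_fraction of it from natural patches -> development uses
    catB <- catA
    target <- change_fraction * total_area
    changed <- logical(np)
    if (target > 0) {
      take_until <- function(cand, goal) {
        got <- 0; sel <- integer(0)
        for (p in cand) {
          if (got >= goal) break
          # stop before overshooting more than the undershoot
          if (got + free_area[p] - goal > goal - got) break
          sel <- c(sel, p); got <- got + free_area[p]
        }
        sel
      }
      nat <- sample(which(catA == "natural" & free_area > 0))
      oth <- sample(which(catA != "natural" & free_area > 0))
      dev_sel <- take_until(nat, dev_fraction * target)
      got_dev <- sum(free_area[dev_sel])
      oth_sel <- take_until(oth, target - got_dev)
      catB[dev_sel] <- sample(c("agriculture", "transportation", "artificial"),
                              length(dev_sel), replace = TRUE)
      for (p in oth_sel)
        catB[p] <- sample(setdiff(LU4, catA[p]), 1L)
      # guard against a no-op relabel (natural -> natural impossible above)
      changed[c(dev_sel, oth_sel)] <- TRUE
    }
    achieved <- sum(free_area[catA != catB]) / total_area

    # decompose the extent into the cut grid of patch and strip edges; every
    # small rectangle is homogeneous (transportation strip or patch interior)
    xc <- sort(unique(c(xb, as.vector(strip_x))))
    yc <- sort(unique(c(yb, as.vector(strip_y))))
    mx <- (xc[-1] + xc[-length(xc)]) / 2
    my <- (yc[-1] + yc[-length(yc)]) / 2
    in_band <- function(m, ints) {
      hit <- rep(FALSE, length(m))
      for (s in seq_len(nrow(ints))) hit <- hit | (m > ints[s, 1] & m < ints[s, 2])
      hit
    }
    sx <- in_band(mx, strip_x); sy <- in_band(my, strip_y)
    ix <- findInterval(mx, xb, all.inside = TRUE)
    iy <- findInterval(my, yb, all.inside = TRUE)
    gx <- rep(seq_along(mx), each = length(my))
    gy <- rep(seq_along(my), times = length(mx))
    is_strip <- sx[gx] | sy[gy]
    pid <- (ix[gx] - 1L) * nr + iy[gy]
    rects <- data.frame(xmin = xc[gx], xmax = xc[gx + 1L],
                        ymin = yc[gy], ymax = yc[gy + 1L])
    cA <- ifelse(is_strip, "transportation", catA[pid])
    cB <- ifelse(is_strip, "transportation", catB[pid])

    # catmat indexed [iy, ix] for O(1) point lookup
    mkmat <- function(cat) {
      m <- matrix(NA_character_, nrow = length(my), ncol = length(mx))
      m[cbind(gy, gx)] <- cat
      m
    }
    layerA <- structure(list(category = cA, rects = rects,
                             xcuts = xc, ycuts = yc, catmat = mkmat(cA)),
                        class = "landuse_layer")
    layerB <- structure(list(category = cB, rects = rects,
                             xcuts = xc, ycuts = yc, catmat = mkmat(cB)),
                        class = "landuse_layer")

    structure(list(
      extent = extent, landuseA = layerA, landuseB = layerB, roads = roads,
      crs_note = "planar meters",
      params = list(seed = as.integer(seed), n_patches = n_patches,
                    change_fraction = change_fraction,
                    road_spacing = road_spacing, road_halfwidth = road_halfwidth,
                    shares = shares, dev_fraction = dev_fraction),
      meta = list(achieved_change_fraction = achieved,
                  patch_grid = c(nr = nr, nc = nc))
    ), class = "landscape_bundle")
  })
}

#' @export
print.landscape_bundle <- function(x, ...) {
  cat("Synthetic landscape bundle (", x$crs_note, ")\n", sep = "")
  cat(sprintf("  extent: [%g, %g] x [%g, %g] m\n",
              x$extent[1], x$extent[2], x$extent[3], x$extent[4]))
  cat(sprintf("  polygons per layer: %d; road segments: %d\n",
              length(x$landuseA$category), nrow(x$roads)))
  cat(sprintf("  changed-area fraction: %.4f (requested %.4f)\n",
              x$meta$achieved_change_fraction, x$params$change_fraction))
  invisible(x)
}

#' Place sampling tubes in two survey waves
#'
#' Places `tubes_per_cell` tubes uniformly at random in every cell of the
#' surveillance grid for wave 1, and re-places each tube for wave 2 within
#' `jitter` meters (clamped to the same cell), mimicking tube locations that
#' change slightly between survey years.  Tubes falling within the
#' transportation strip of a road are snapped onto the road centerline
#' (surveillance tubes are set along roads), which gives transportation-land
#' tubes a road distance of exactly zero.
#'
#' @param bundle a [generate_landscape()] bundle.
#' @param grid a [grid_spec()].
#' @param tubes_per_cell 1 or 2 tubes per cell and wave.
#' @param jitter maximum per-coordinate wave-2 displacement, meters
#'   (must be `< cell_size / 2`).
#' @param seed integer seed.
#' @param snap_to_road snap tubes inside the road strip onto the centerline.
#' @return list with data frames `wave1` and `wave2`
#'   (`tube_id, x, y, period, scale`), `scale` unset (`NA`) until simulated.
#' @export
place_tubes <- function(bundle, grid, tubes_per_cell = 2, jitter = 20,
                        seed = 1L, snap_to_road = TRUE) {
  stopifnot(inherits(bundle, "landscape_bundle"), inherits(grid, "grid_spec"))
  if (!tubes_per_cell %in% c(1L, 2L))
    stop_fmt("tubes_per_cell must be 1 or 2, got %s", tubes_per_cell)
  if (jitter >= grid$cell_size / 2)
    stop_fmt("jitter (%g) must be < cell_size/2 (%g)", jitter, grid$cell_size / 2)
  with_seed(seed, {
    cells <- expand.grid(i = seq_len(grid$n_rows) - 1L,
                         j = seq_len(grid$n_cols) - 1L)
    cells <- cells[rep(seq_len(nrow(cells)), each = tubes_per_cell), ]
    n <- nrow(cells)
    cs <- grid$cell_size
    eps <- cs * 1e-9
    x0 <- grid$origin_x + cells$j * cs
    y0 <- grid$origin_y + cells$i * cs
    x1 <- x0 + stats::runif(n) * (cs - eps)
    y1 <- y0 + stats::runif(n) * (cs - eps)
    x2 <- pmin(pmax(x1 + stats::runif(n, -jitter, jitter), x0), x0 + cs - eps)
    y2 <- pmin(pmax(y1 + stats::runif(n, -jitter, jitter), y0), y0 + cs - eps)
    if (snap_to_road) {
      hw <- bundle$params$road_halfwidth
      snap <- function(x, y) {
        pr <- project_to_roads(x, y, bundle$roads)
        onr <- pr$dist <= hw
        x[onr] <- pr$x[onr]; y[onr] <- pr$y[onr]
        list(x = x, y = y)
      }
      s1 <- snap(x1, y1); x1 <- s1$x; y1 <- s1$y
      s2 <- snap(x2, y2); x2 <- s2$x; y2 <- s2$y
    }
    ids <- sprintf("T%06d", seq_len(n))
    list(
      wave1 = data.frame(tube_id = ids, x = x1, y = y1,
                         period = "wave1", scale = NA_integer_),
      wave2 = data.frame(tube_id = ids, x = x2, y = y2,
                         period = "wave2", scale = NA_integer_)
    )
  })
}

#' Data-generating truth for the SIRH risk model
#'
#' Describes the logistic data-generating process on the cell level:
#' `logit P(SIRH) = beta0 + category offset + g_dist(d; category) +
#' spatial_field(x, y)`.  Natural land cover is the reference category and its
#' offset must be exactly zero.  Defaults reproduce the parametric odds ratios
#' of the fitted surveillance model (agriculture 2.247, transportation 1.346,
#' land-use change 1.354, artificial 1.251, intercept 1.547) with no nonlinear
#' terms.
#'
#' @param beta0 intercept on the log-odds scale.
#' @param category_logodds named log-odds offsets for the five categories;
#'   `natural` must be 0.
#' @param g_dist `NULL` (no distance effect), a function of distance, or a
#'   named list of per-category functions (missing categories get 0).
#' @param spatial_field `NULL` or a bounded function `f(x, y)` of planar
#'   coordinates, log-odds scale.
#' @return object of class `true_model`.
#' @export
true_model <- function(beta0 = log(1.547),
                       category_logodds = c(natural = 0,
                                            artificial = log(1.251),
                                            transportation = log(1.346),
                                            agriculture = log(2.247),
                                            change = log(1.354)),
                       g_dist = NULL, spatial_field = NULL) {
  check_number(beta0, "beta0")
  if (is.null(names(category_logodds)) || !all(LU5 %in% names(category_logodds)))
    stop_fmt("category_logodds must be named with all five land-use categories")
  if (category_logodds[["natural"]] != 0)
    stop_fmt("the natural land cover offset is the reference and must be exactly 0")
  if (!is.null(g_dist) && !is.function(g_dist) && !is.list(g_dist))
    stop_fmt("g_dist must be NULL, a function, or a named list of functions")
  structure(list(beta0 = beta0,
                 category_logodds = category_logodds[LU5],
                 g_dist = g_dist, spatial_field = spatial_field),
            class = "true_model")
}

# Evaluate the truth's linear predictor for vectors of covariates.
true_linpred <- function(truth, category, road_dist, x, y) {
  eta <- truth$beta0 + unname(truth$category_logodds[as.character(category)])
  if (!is.null(truth$g_dist)) {
    if (is.function(truth$g_dist)) {
      eta <- eta + truth$g_dist(road_dist)
    } else {
      for (lv in names(truth$g_dist)) {
        sel <- as.character(category) == lv
        if (any(sel)) eta[sel] <- eta[sel] + truth$g_dist[[lv]](road_dist[sel])
      }
    }
  }
  if (!is.null(truth$spatial_field)) eta <- eta + truth$spatial_field(x, y)
  eta
}

#' Simulate per-cell SIRH outcomes from a data-generating truth
#'
#' Evaluates the true logistic model at each cell (using the covariates of the
#' cell's first wave-2 tube; tubes within one 200 m cell have near-identical
#' covariates) and draws one Bernoulli SIRH indicator per cell.
#'
#' @param tubes wave-2 tube data frame with attached covariates (`landuse5`,
#'   `road_dist`, plus `x`, `y`).
#' @param truth a [true_model()].
#' @param grid a [grid_spec()] defining the cells.
#' @param seed integer seed.
#' @return data frame `i, j, p, sirh` with one row per sampled cell.
#' @export
simulate_sirh_labels <- function(tubes, truth, grid, seed = 1L) {
  need <- c("landuse5", "road_dist", "x", "y")
  miss <- setdiff(need, names(tubes))
  if (length(miss))
    stop_fmt("covariates must be attached before simulation; missing: %s",
             paste(miss, collapse = ", "))
  idx <- cell_index(tubes$x, tubes$y, grid)
  key <- paste(idx$i, idx$j)
  first <- !duplicated(key)
  cells <- data.frame(i = idx$i[first], j = idx$j[first])
  eta <- true_linpred(truth, tubes$landuse5[first], tubes$road_dist[first],
                      tubes$x[first], tubes$y[first])
  p <- stats::plogis(eta)
  with_seed(seed, {
    cells$p <- p
    cells$sirh <- stats::rbinom(nrow(cells), 1L, p)
    cells
  })
}

# Consistent severity-scale pairs per label (wave1 scale, wave2 scale):
# SIRH  <=> s2 > s1 or s1 = s2 = 3; USIRL <=> s2 <= s1 and not both 3.
SIRH_PAIRS <- matrix(c(0,1, 0,2, 0,3, 1,2, 1,3, 2,3, 3,3), ncol = 2, byrow = TRUE)
USIRL_PAIRS <- matrix(c(0,0, 1,0, 1,1, 2,0, 2,1, 2,2, 3,0, 3,1, 3,2),
                      ncol = 2, byrow = TRUE)

#' Draw severity-scale pairs consistent with SIRH/USIRL labels
#'
#' Inverts the cell classification rule: for each labelled cell a
#' (wave-1, wave-2) severity pair is drawn uniformly from the set of pairs
#' consistent with the label, so classifying the generated pair recovers the
#' label exactly.
#'
#' @param labels character (`"SIRH"`/`"USIRL"`), logical, or 0/1 vector.
#' @param seed integer seed.
#' @return data frame with integer columns `s1`, `s2`.
#' @export
labels_to_severity <- function(labels, seed = 1L) {
  if (is.numeric(labels) || is.logical(labels))
    labels <- ifelse(as.logical(labels), "SIRH", "USIRL")
  if (!all(labels %in% c("SIRH", "USIRL")))
    stop_fmt("labels must be SIRH or USIRL")
  with_seed(seed, {
    n <- length(labels)
    s1 <- integer(n); s2 <- integer(n)
    is_s <- labels == "SIRH"
    ki <- sample.int(nrow(SIRH_PAIRS), sum(is_s), replace = TRUE)
    ku <- sample.int(nrow(USIRL_PAIRS), sum(!is_s), replace = TRUE)
    s1[is_s] <- SIRH_PAIRS[ki, 1]; s2[is_s] <- SIRH_PAIRS[ki, 2]
    s1[!is_s] <- USIRL_PAIRS[ku, 1]; s2[!is_s] <- USIRL_PAIRS[ku, 2]
    data.frame(s1 = s1, s2 = s2)
  })
}

#' Assign per-tube severity scales from per-cell scales
#'
#' Each cell's designated maximum scale is given to the first tube in the
#' cell; any further tubes draw a scale uniformly between 0 and the cell
#' maximum, so the per-cell maximum over tubes equals the designated scale.
#'
#' @param tubes tube data frame for one wave (`x`, `y`, `scale`).
#' @param cell_scales data frame `i, j, s` of per-cell maximum scales.
#' @param grid a [grid_spec()].
#' @param seed integer seed.
#' @return `tubes` with `scale` filled in.
#' @export
assign_tube_scales <- function(tubes, cell_scales, grid, seed = 1L) {
  idx <- cell_index(tubes$x, tubes$y, grid)
  key <- paste(idx$i, idx$j)
  ckey <- paste(cell_scales$i, cell_scales$j)
  m <- match(key, ckey)
  if (anyNA(m)) stop_fmt("tube found in a cell with no designated scale")
  smax <- cell_scales$s[m]
  with_seed(seed, {
    sc <- integer(nrow(tubes))
    first <- !duplicated(key)
    sc[first] <- smax[first]
    rest <- which(!first)
    if (length(rest))
      sc[rest] <- vapply(smax[rest], function(s) sample.int(s + 1L, 1L) - 1L, 1L)
    tubes$scale <- sc
    tubes
  })
}

#' Simulate a model-ready tube table directly from stated frequencies
#'
#' A distributional shortcut used for simulation studies: instead of building
#' a landscape, categories are drawn from given frequencies, road distances
#' from a given sampler, coordinates uniformly over the extent, and the binary
#' SIRH outcome from the [true_model()].  Default frequencies match the
#' surveillance category distribution (transportation 1814, agriculture 1743,
#' natural 1730, change 1193, artificial 438 of 6918 tubes).
#'
#' @param n number of tubes.
#' @param truth a [true_model()].
#' @param category_freq named category probabilities (normalized internally).
#' @param road_dist_sampler `function(n, category)` returning distances (m).
#' @param extent `c(xmin, xmax, ymin, ymax)` for coordinates.
#' @param seed integer seed.
#' @return model-row data frame: `tube_id, y, landuse5, road_dist, x, y_coord`.
#' @export
simulate_tube_table <- function(n, truth = true_model(),
                                category_freq = c(transportation = 1814,
                                                  agriculture = 1743,
                                                  natural = 1730,
                                                  change = 1193,
                                                  artificial = 438),
                                road_dist_sampler = function(n, category)
                                  stats::runif(n, 0, 800),
                                extent = c(0, 11600, 0, 11400),
                                seed = 1L) {
  stopifnot(all(names(category_freq) %in% LU5))
  with_seed(seed, {
    cat <- sample(names(category_freq), n, replace = TRUE,
                  prob = category_freq / sum(category_freq))
    d <- road_dist_sampler(n, cat)
    x <- stats::runif(n, extent[1], extent[2])
    y <- stats::runif(n, extent[3], extent[4])
    eta <- true_linpred(truth, cat, d, x, y)
    data.frame(tube_id = sprintf("S%06d", seq_len(n)),
               y = stats::rbinom(n, 1L, stats::plogis(eta)),
               landuse5 = landuse5_factor(cat),
               road_dist = d, x = x, y_coord = y)
  })
}
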