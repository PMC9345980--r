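# The three risk models and the result summaries built on them.
#
# Model GLM : logit(y) ~ landuse5 + road_dist + x + y + x*y   (all linear)
# Model GAM1: logit(y) ~ landuse5 + s(road_dist) + te(x, y)
# Model GAM2: logit(y) ~ landuse5 + s(road_dist, by = landuse5) + te(x, y)
#
# Coordinates are standardized internally (meters have magnitude ~1e4 and the
# x*y product ~1e8, which would make the GLM normal equations needlessly
# ill-conditioned); the scaling is stored on the fit and applied to new data.

#' Fit one of the three SIRH risk models
#'
#' @param name `"GLM"`, `"GAM1"` or `"GAM2"`.
#' @param table model-row table (`y`, `landuse5`, `road_dist`, `x`, `y_coord`).
#' @param k_dist basis dimension of distance smooths.
#' @param k_spatial marginal basis dimension of the spatial tensor smooth.
#' @param lambda optional fixed smoothing parameters (else GCV).
#' @param control a [pslogit_control()].
#' @return a [pslogit()] fit, augmented with the coordinate scaling and a
#'   component map (landuse / dist / spatial) used by [predict_components()].
#' @export
build_model <- function(name = c("GLM", "GAM1", "GAM2"), table,
                        k_dist = 10, k_spatial = 6, lambda = NULL,
                        control = pslogit_control()) {
  name <- match.arg(name)
  need <- c("y", "landuse5", "road_dist", "x", "y_coord")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop_fmt("model table is missing columns: %s", paste(miss, collapse = ", "))
  table$landuse5 <- landuse5_factor(as.character(table$landuse5))
  empty <- levels(table$landuse5)[tabulate(table$landuse5, 5) == 0]
  if (length(empty))
    stop_fmt("land-use level with no observations: %s", paste(empty, collapse = ", "))

  cs <- list(x_mean = mean(table$x), x_sd = stats::sd(table$x),
             y_mean = mean(table$y_coord), y_sd = stats::sd(table$y_coord))
  table <- add_scaled_coords(table, cs)

  fm <- switch(name,
    GLM  = y ~ landuse5 + road_dist + xs + ys + xys,
    GAM1 = bquote(y ~ landuse5 + s(road_dist, k = .(k_dist)) +
                    te(xs, ys, k = .(k_spatial))),
    GAM2 = bquote(y ~ landuse5 + s(road_dist, k = .(k_dist), by = landuse5) +
                    te(xs, ys, k = .(k_spatial))))
  if (is.call(fm) || is.name(fm)) fm <- eval(fm)
  fit <- pslogit(stats::as.formula(fm), table, lambda = lambda, control = control)

  # component of each block: landuse (incl. intercept), dist, spatial
  comp <- vapply(fit$design$blocks, function(b) {
    lab <- b$label
    if (grepl("road_dist", lab)) "dist"
    else if (grepl("xs|ys|te\\(", lab)) "spatial"
    else "landuse"
  }, "")
  fit$model_name <- name
  fit$coord_scale <- cs
  fit$component_map <- comp
  fit$covar_means <- list(x = cs$x_mean, y_coord = cs$y_mean,
                          road_dist_max = max(table$road_dist))
  fit
}

add_scaled_coords <- function(table, cs) {
  table$xs <- (table$x - cs$x_mean) / cs$x_sd
  table$ys <- (table$y_coord - cs$y_mean) / cs$y_sd
  table$xys <- table$xs * table$ys
  table
}

#' Component-wise linear-predictor decomposition
#'
#' Splits predictions from a [build_model()] fit into the land-use
#' (parametric, including the intercept), road-distance, and spatial
#' components.  The three components sum exactly to the full linear
#' predictor.
#'
#' @param fit a [build_model()] fit.
#' @param newdata data frame with `landuse5`, `road_dist`, `x`, `y_coord`.
#' @return data frame `lp_landuse, lp_dist, lp_spatial, lp, p`.
#' @export
predict_components <- function(fit, newdata) {
  if (is.null(fit$component_map))
    stop_fmt("predict_components requires a fit produced by build_model()")
  newdata$landuse5 <- landuse5_factor(as.character(newdata$landuse5))
  nd <- add_scaled_coords(newdata, fit$coord_scale)
  tm <- predict(fit, nd, type = "terms")
  agg <- function(cp) {
    cols <- which(fit$component_map == cp)
    if (!length(cols)) return(rep(0, nrow(tm)))
    rowSums(tm[, cols, drop = FALSE])
  }
  lp_landuse <- agg("landuse"); lp_dist <- agg("dist"); lp_spatial <- agg("spatial")
  lp <- lp_landuse + lp_dist + lp_spatial
  data.frame(lp_landuse = lp_landuse, lp_dist = lp_dist,
             lp_spatial = lp_spatial, lp = lp, p = stats::plogis(lp))
}

#' Compare fitted risk models
#'
#' AIC table plus analysis-of-deviance rows for the nested chain in the order
#' given (GLM within GAM1 within GAM2); the selected model minimizes AIC.
#'
#' @param fits named list of fits in nesting order, e.g.
#'   `list(GLM = ..., GAM1 = ..., GAM2 = ...)`.
#' @return list of class `sirh_comparison`: `aic` table, `anova` rows,
#'   `selected` model name.
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 2, !is.null(names(fits)))
  n <- vapply(fits, `[[`, 0, "nobs")
  if (length(unique(n)) != 1L)
    stop_fmt("fits must share identical rows (n: %s)", paste(n, collapse = ", "))
  aic <- data.frame(model = names(fits),
                    edf = vapply(fits, `[[`, 0, "edf_total"),
                    deviance = vapply(fits, `[[`, 0, "deviance"),
                    AIC = vapply(fits, `[[`, 0, "aic"), row.names = NULL)
  an <- NULL
  for (k in seq_len(length(fits) - 1L)) {
    row <- anova_compare(fits[[k]], fits[[k + 1L]])
    row <- cbind(comparison = paste(names(fits)[k + 1L], "vs", names(fits)[k]), row)
    an <- rbind(an, row)
  }
  structure(list(aic = aic, anova = an,
                 selected = aic$model[which.min(aic$AIC)]),
            class = "sirh_comparison")
}

#' @export
print.sirh_comparison <- function(x, ...) {
  cat("Model comparison (binomial additive risk models)\n")
  print(format(x$aic, digits = 6), row.names = FALSE)
  cat("\nAnalysis of deviance (nested chain)\n")
  print(format(x$anova, digits = 4), row.names = FALSE)
  cat("\nSelected (min AIC):", x$selected, "\n")
  invisible(x)
}

#' Label-by-category contingency table and Pearson chi-square
#'
#' Cross-tabulates SIRH/USIRL labels against the five land-use categories,
#' reports row percentages (rounded half-up to one decimal, matching table
#' formatting conventions) and the Pearson chi-square test without
#' continuity correction.
#'
#' @param x either a labelled model table (`y`, `landuse5`) or a counts
#'   matrix with categories in rows and columns `USIRL`, `SIRH`.
#' @return list `counts` (categories x 2), `row_pct`, `chisq`, `df`,
#'   `p_value`.
#' @export
contingency_and_chi2 <- function(x) {
  if (is.matrix(x)) {
    counts <- x
    if (is.null(colnames(counts))) colnames(counts) <- c("USIRL", "SIRH")
  } else {
    tab <- table(category = landuse5_factor(as.character(x$landuse5)),
                 label = factor(ifelse(x$y == 1, "SIRH", "USIRL"),
                                levels = c("USIRL", "SIRH")))
    counts <- unclass(tab)
  }
  keep <- rowSums(counts) > 0
  if (!all(keep)) {
    message("empty categories dropped from chi-square: ",
            paste(rownames(counts)[!keep], collapse = ", "))
    counts <- counts[keep, , drop = FALSE]
  }
  ct <- stats::chisq.test(counts, correct = FALSE)
  row_pct <- round_half_up(100 * counts / rowSums(counts), 1)
  list(counts = counts, row_pct = row_pct,
       chisq = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}

#' Severity-scale distribution per survey wave
#'
#' @param tubes tube data frame with `period` and `scale`, or a list of such
#'   frames (waves bound together).
#' @return data frame `period, scale, n, pct` with percentages of the wave
#'   total rounded half-up to one decimal.
#' @export
severity_summary <- function(tubes) {
  if (is.list(tubes) && !is.data.frame(tubes)) tubes <- do.call(rbind, tubes)
  if (!all(tubes$scale %in% 0:3)) stop_fmt("severity scales must be 0-3")
  tab <- table(period = tubes$period, scale = factor(tubes$scale, levels = 0:3))
  out <- as.data.frame(tab, responseName = "n")
  tot <- stats::ave(out$n, out$period, FUN = sum)
  out$pct <- round_half_up(100 * out$n / tot, 1)
  out$scale <- as.integer(as.character(out$scale))
  out[order(out$period, out$scale), ]
}

#' Percentage share of an area in a total
#'
#' @param area,total areas in the same unit (e.g. km^2).
#' @return percentage rounded half-up to one decimal.
#' @export
area_share_pct <- function(area, total) round_half_up(100 * area / total, 1)

#' Land-use transition table for tubes in the change category
#'
#' For tubes whose land-use category differs between the two reference years,
#' tabulates the ordered (year A -> year B) transition pairs as percentages
#' and aggregates the development-related share (natural converted to
#' agriculture, transportation, or artificial).
#'
#' @param x,y coordinates of tubes in the change category (meters).
#' @param layerA,layerB the two land-use layers.
#' @return list `pairs` (data frame `from, to, n, pct`),
#'   `development_related_pct`.
#' @export
change_flow_summary <- function(x, y, layerA, layerB) {
  a <- category_at_point(x, y, layerA)
  b <- category_at_point(x, y, layerB)
  if (any(a == b))
    stop_fmt("%d tubes are not in the change category", sum(a == b))
  tab <- as.data.frame(table(from = a, to = b), responseName = "n")
  tab <- tab[tab$n > 0, , drop = FALSE]
  tab$pct <- round_half_up(100 * tab$n / sum(tab$n), 1)
  dev <- a == "natural" & b %in% c("agriculture", "transportation", "artificial")
  list(pairs = tab[order(-tab$n), ],
       development_related_pct = round_half_up(100 * mean(dev), 1))
}

#' Distance range over which predicted SIRH probability stays above a level
#'
#' Scans the fitted distance-probability curve from 0 m upward (1 m steps by
#' default) and returns the largest distance `d*` such that the predicted
#' probability is at least `p0` everywhere on `[0, d*]`, refining the
#' crossing by root finding.  Other covariates are held at reference values:
#' the curve's own category and the mean training coordinates.
#'
#' @param object a [build_model()] fit, or a function `p(d)` for analytic
#'   curves.
#' @param category land-use category of the curve (ignored for functions).
#' @param p0 probability level in (0, 1).
#' @param max_dist scan limit (m); defaults to the training maximum for fits.
#' @param step scan resolution (m).
#' @return list `d_star` (m; 0 with a `note` if the curve starts below
#'   `p0`), `curve` (data frame `dist, p`), `p0`.
#' @export
distance_threshold <- function(object, category = "natural", p0 = 0.6,
                               max_dist = NULL, step = 1) {
  check_number(p0, "p0", 1e-12, 1 - 1e-12)
  if (is.function(object)) {
    pfun <- object
    if (is.null(max_dist)) max_dist <- 1000
  } else {
    if (is.null(fit_ok <- object$converged) || !fit_ok)
      warning("distance_threshold on a non-converged fit")
    if (is.null(max_dist)) max_dist <- object$covar_means$road_dist_max
    pfun <- function(d) {
      nd <- data.frame(landuse5 = category, road_dist = d,
                       x = object$covar_means$x,
                       y_coord = object$covar_means$y_coord)
      predict_components(object, nd)$p
    }
  }
  dg <- seq(0, max_dist, by = step)
  pg <- pfun(dg)
  curve <- data.frame(dist = dg, p = pg)
  if (pg[1] < p0)
    return(list(d_star = 0, curve = curve, p0 = p0,
                note = "predicted probability at 0 m is below p0"))
  below <- which(pg < p0)
  if (!length(below))
    return(list(d_star = max_dist, curve = curve, p0 = p0,
                note = "probability stays above p0 over the whole scan range"))
  k <- below[1]
  d_star <- stats::uniroot(function(d) pfun(d) - p0,
                           lower = dg[k - 1], upper = dg[k],
                           tol = 1e-8)$root
  list(d_star = d_star, curve = curve, p0 = p0, note = NULL)
}

#' Component-wise risk surface on the surveillance grid
#'
#' Evaluates a fitted risk model at every cell center of the grid, attaching
#' covariates from the landscape bundle, and reports the probability plus the
#' land-use, road-distance and spatial linear-predictor components (which sum
#' to the total linear predictor).
#'
#' @param fit a [build_model()] fit.
#' @param grid a [grid_spec()].
#' @param bundle the landscape bundle providing land-use layers and roads.
#' @return data frame
#'   `i, j, x_center, y_center, p, lp_landuse, lp_dist, lp_spatial`.
#' @export
risk_surface <- function(fit, grid, bundle) {
  cells <- expand.grid(i = seq_len(grid$n_rows) - 1L,
                       j = seq_len(grid$n_cols) - 1L)
  xc <- grid$origin_x + (cells$j + 0.5) * grid$cell_size
  yc <- grid$origin_y + (cells$i + 0.5) * grid$cell_size
  nd <- data.frame(
    landuse5 = landuse5(xc, yc, bundle$landuseA, bundle$landuseB),
    road_dist = nearest_road_distance(xc, yc, bundle$roads),
    x = xc, y_coord = yc)
  pc <- predict_components(fit, nd)
  data.frame(i = cells$i, j = cells$j, x_center = xc, y_center = yc,
             p = pc$p, lp_landuse = pc$lp_landuse, lp_dist = pc$lp_dist,
             lp_spatial = pc$lp_spatial)
}
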