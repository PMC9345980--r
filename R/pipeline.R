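# YAML-configured pipeline: simulate -> quantify -> covariates -> fit ->
# compare -> report.  Every stage reads only the config and its upstream
# artifacts, uses a per-stage substream of the single global seed, and is
# idempotent: rerunning with the same inputs rewrites identical files.

#' Read and validate a pipeline configuration
#'
#' @param path YAML config file (see `inst/extdata/config-default.yml`).
#' @return validated config list of class `sirh_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_fmt("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

#' @rdname read_config
#' @param cfg a config list.
#' @export
validate_config <- function(cfg) {
  fail <- function(field, msg) stop_fmt("config field '%s': %s", field, msg)
  req <- function(field) {
    parts <- strsplit(field, ".", fixed = TRUE)[[1]]
    v <- cfg
    for (p in parts) {
      if (is.null(v[[p]])) fail(field, "is required")
      v <- v[[p]]
    }
    v
  }
  num <- function(field, lower = -Inf, upper = Inf) {
    v <- req(field)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      fail(field, "must be a single finite number")
    if (v < lower || v > upper)
      fail(field, sprintf("must be in [%g, %g]", lower, upper))
    v
  }
  num("seed")
  ext <- req("extent")
  if (!is.numeric(unlist(ext)) || length(unlist(ext)) != 4)
    fail("extent", "must be [xmin, xmax, ymin, ymax]")
  ext <- as.numeric(unlist(ext))
  if (ext[2] <= ext[1] || ext[4] <= ext[3])
    fail("extent", "must have positive width and height")
  num("grid.cell_size", lower = 1e-9)
  num("generator.n_patches", lower = 1)
  num("generator.change_fraction", 0, 1 - 1e-12)
  num("generator.road_spacing", lower = 1e-9)
  num("generator.road_halfwidth", lower = 0)
  tpc <- num("generator.tubes_per_cell", 1, 2)
  if (!tpc %in% c(1, 2)) fail("generator.tubes_per_cell", "must be 1 or 2")
  num("generator.jitter", 0, num("grid.cell_size") / 2)
  num("truth.beta0_or", lower = 1e-12)
  ors <- req("truth.or")
  if (!all(c("artificial", "transportation", "agriculture", "change") %in% names(ors)))
    fail("truth.or", "must name artificial, transportation, agriculture, change")
  num("model.k_dist", lower = 4)
  num("model.k_spatial", lower = 4)
  req("out_dir")
  cfg$extent <- ext
  structure(cfg, class = "sirh_config")
}

cfg_truth <- function(cfg) {
  ors <- cfg$truth$or
  g <- NULL
  if (!is.null(cfg$truth$dist_effect)) {
    g <- lapply(cfg$truth$dist_effect, function(sp) {
      switch(sp$type,
        exp_decay = local({ a <- sp$a; s <- sp$scale
                            function(d) a * exp(-d / s) }),
        linear    = local({ b <- sp$b; function(d) b * d }),
        stop_fmt("unknown dist_effect type '%s'", sp$type))
    })
  }
  sf <- NULL
  if (!is.null(cfg$truth$spatial)) {
    sp <- cfg$truth$spatial
    if (!identical(sp$type, "gauss_bump"))
      stop_fmt("unknown spatial truth type '%s'", sp$type)
    sf <- local({ amp <- sp$amp; cx <- sp$cx; cy <- sp$cy; s <- sp$scale
                  function(x, y) amp * exp(-((x - cx)^2 + (y - cy)^2) / (2 * s^2)) })
  }
  true_model(beta0 = log(cfg$truth$beta0_or),
             category_logodds = c(natural = 0,
                                  artificial = log(ors$artificial),
                                  transportation = log(ors$transportation),
                                  agriculture = log(ors$agriculture),
                                  change = log(ors$change)),
             g_dist = g, spatial_field = sf)
}

cfg_grid <- function(cfg) grid_from_extent(cfg$extent, cfg$grid$cell_size)

cfg_bundle <- function(cfg) {
  gn <- cfg$generator
  shares <- if (is.null(gn$shares)) formals(generate_landscape)$shares
            else unlist(gn$shares)
  if (is.call(shares) || is.name(shares)) shares <- eval(shares)
  generate_landscape(seed = cfg$seed + 1L, extent = cfg$extent,
                     n_patches = gn$n_patches,
                     change_fraction = gn$change_fraction,
                     road_spacing = gn$road_spacing,
                     road_halfwidth = gn$road_halfwidth,
                     shares = shares,
                     dev_fraction = gn$dev_fraction %||% 0.616)
}

out_path <- function(cfg, ...) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  file.path(cfg$out_dir, ...)
}

log_line <- function(cfg, ...) {
  msg <- sprintf("[%s] %s", "sirh-pipeline", sprintf(...))
  message(msg)
  cat(msg, "\n", file = out_path(cfg, "run.log"), append = TRUE)
}

#' Pipeline stages
#'
#' `stage_simulate` generates the landscape, tubes and severity scales;
#' `stage_quantify` grids, classifies and labels; `stage_covariates` attaches
#' the land-use-change and road-distance covariates; `stage_fit` fits one of
#' the three models; `stage_compare` compares stored fits; `stage_report`
#' writes descriptive tables, distance thresholds, risk surfaces and figures.
#' All artifacts live under `cfg$out_dir`.
#'
#' @param cfg a validated [read_config()] list.
#' @return invisibly, the main artifact path(s) of the stage.
#' @export
stage_simulate <- function(cfg) {
  bundle <- cfg_bundle(cfg)
  grid <- cfg_grid(cfg)
  tubes <- place_tubes(bundle, grid, tubes_per_cell = cfg$generator$tubes_per_cell,
                       jitter = cfg$generator$jitter, seed = cfg$seed + 2L)
  w2 <- tubes$wave2
  cov2 <- data.frame(landuse5 = landuse5(w2$x, w2$y, bundle$landuseA, bundle$landuseB),
                     road_dist = nearest_road_distance(w2$x, w2$y, bundle$roads),
                     x = w2$x, y = w2$y)
  cells <- simulate_sirh_labels(cov2, cfg_truth(cfg), grid, seed = cfg$seed + 3L)
  sev <- labels_to_severity(cells$sirh, seed = cfg$seed + 4L)
  w1 <- assign_tube_scales(tubes$wave1, data.frame(i = cells$i, j = cells$j, s = sev$s1),
                           grid, seed = cfg$seed + 5L)
  w2 <- assign_tube_scales(w2, data.frame(i = cells$i, j = cells$j, s = sev$s2),
                           grid, seed = cfg$seed + 6L)
  write_tubes_csv(rbind(w1, w2), out_path(cfg, "tubes.csv"))
  write_landuse_geojson(bundle$landuseA, out_path(cfg, "landuseA.geojson"))
  write_landuse_geojson(bundle$landuseB, out_path(cfg, "landuseB.geojson"))
  write_roads_geojson(bundle$roads, out_path(cfg, "roads.geojson"))
  jsonlite::write_json(
    list(seed = cfg$seed, n_tubes_per_wave = nrow(w1),
         achieved_change_fraction = bundle$meta$achieved_change_fraction,
         config = unclass(cfg)),
    out_path(cfg, "simulate_meta.json"), auto_unbox = TRUE, digits = NA)
  log_line(cfg, "simulate: %d tubes per wave, change fraction %.4f",
           nrow(w1), bundle$meta$achieved_change_fraction)
  invisible(out_path(cfg, "tubes.csv"))
}

#' @rdname stage_simulate
#' @export
stage_quantify <- function(cfg) {
  if (!file.exists(out_path(cfg, "tubes.csv")))
    stop_fmt("missing upstream artifact tubes.csv; run the simulate stage first")
  tubes <- read_tubes_csv(out_path(cfg, "tubes.csv"))
  grid <- cfg_grid(cfg)
  w1 <- tubes[tubes$period == "wave1", ]
  w2 <- tubes[tubes$period == "wave2", ]
  cells <- cell_states(w1, w2, grid)
  lab <- label_tubes(w2, cells, grid)
  write_cells_csv(cells, out_path(cfg, "cells.csv"))
  utils::write.csv(lab, out_path(cfg, "labelled_tubes.csv"),
                   row.names = FALSE, quote = FALSE)
  log_line(cfg, "quantify: %d cells (%d SIRH, %d USIRL, %d undefined); %d tubes labelled, %d excluded",
           nrow(cells), sum(cells$label == "SIRH"), sum(cells$label == "USIRL"),
           sum(cells$label == "undefined"), nrow(lab), attr(lab, "excluded_n"))
  invisible(out_path(cfg, "cells.csv"))
}

#' @rdname stage_simulate
#' @export
stage_covariates <- function(cfg) {
  p <- out_path(cfg, "labelled_tubes.csv")
  if (!file.exists(p))
    stop_fmt("missing upstream artifact labelled_tubes.csv; run the quantify stage first")
  lab <- utils::read.csv(p, stringsAsFactors = FALSE)
  bundle <- cfg_bundle(cfg)  # deterministic regeneration from the same seed
  tab <- attach_covariates(lab, bundle, quiet = TRUE)
  write_model_table_csv(tab, out_path(cfg, "model_table.csv"))
  log_line(cfg, "covariates: %d model rows", nrow(tab))
  invisible(out_path(cfg, "model_table.csv"))
}

#' @rdname stage_simulate
#' @param model `"glm"`, `"gam1"` or `"gam2"`.
#' @export
stage_fit <- function(cfg, model = c("glm", "gam1", "gam2")) {
  model <- match.arg(model)
  p <- out_path(cfg, "model_table.csv")
  if (!file.exists(p))
    stop_fmt("missing upstream artifact model_table.csv; run the covariates stage first")
  tab <- read_model_table_csv(p)
  fit <- build_model(toupper(sub("gam", "GAM", model)), tab,
                     k_dist = cfg$model$k_dist, k_spatial = cfg$model$k_spatial)
  saveRDS(fit, out_path(cfg, paste0("fit_", model, ".rds")))
  write_fit_json(fit, out_path(cfg, paste0("fit_", model, ".json")))
  log_line(cfg, "fit %s: deviance %.3f, EDF %.2f, AIC %.3f, converged %s",
           toupper(model), fit$deviance, fit$edf_total, fit$aic, fit$converged)
  invisible(out_path(cfg, paste0("fit_", model, ".json")))
}

#' @rdname stage_simulate
#' @export
stage_compare <- function(cfg) {
  paths <- out_path(cfg, paste0("fit_", c("glm", "gam1", "gam2"), ".rds"))
  if (!all(file.exists(paths)))
    stop_fmt("missing fitted models (%s); run the fit stage for glm, gam1 and gam2",
             paste(basename(paths)[!file.exists(paths)], collapse = ", "))
  fits <- lapply(paths, readRDS)
  names(fits) <- c("GLM", "GAM1", "GAM2")
  cmp <- compare_models(fits)
  jsonlite::write_json(list(aic = cmp$aic, anova = cmp$anova, selected = cmp$selected),
                       out_path(cfg, "comparison.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  writeLines(utils::capture.output(print(cmp)), out_path(cfg, "comparison.txt"))
  log_line(cfg, "compare: selected %s", cmp$selected)
  invisible(out_path(cfg, "comparison.json"))
}

#' @rdname stage_simulate
#' @export
stage_report <- function(cfg) {
  tubes <- read_tubes_csv(out_path(cfg, "tubes.csv"))
  tab <- read_model_table_csv(out_path(cfg, "model_table.csv"))
  best_path <- out_path(cfg, "fit_gam2.rds")
  if (!file.exists(best_path))
    stop_fmt("missing fitted model fit_gam2.rds; run the fit stage first")
  fit <- readRDS(best_path)
  bundle <- cfg_bundle(cfg)
  grid <- cfg_grid(cfg)

  sev <- severity_summary(tubes)
  cont <- contingency_and_chi2(tab)
  thr <- lapply(c(transportation = "transportation", change = "change"),
                function(cat) {
                  t <- distance_threshold(fit, cat, p0 = 0.6)
                  list(category = cat, p0 = 0.6, d_star = t$d_star, note = t$note)
                })
  surf <- risk_surface(fit, grid, bundle)
  utils::write.csv(surf, out_path(cfg, "risk_surface.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(severity = sev,
         contingency = list(counts = as.data.frame(cont$counts),
                            row_pct = as.data.frame(cont$row_pct),
                            chisq = cont$chisq, df = cont$df, p = cont$p_value),
         thresholds = unname(thr)),
    out_path(cfg, "report.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")

  grDevices::png(out_path(cfg, "distance_curves.png"), 900, 450)
  graphics::par(mfrow = c(1, 2))  # device-local; discarded with the device
  for (cat in c("transportation", "change")) {
    t <- distance_threshold(fit, cat, p0 = 0.6)
    graphics::plot(t$curve$dist, t$curve$p, type = "l", ylim = c(0, 1),
                   xlab = "distance to nearest road (m)", ylab = "P(SIRH)",
                   main = cat)
    graphics::abline(h = 0.6, lty = 2)
    if (t$d_star > 0) graphics::abline(v = t$d_star, lty = 3)
  }
  grDevices::dev.off()
  grDevices::png(out_path(cfg, "risk_surface.png"), 700, 650)
  z <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  z[cbind(surf$i + 1L, surf$j + 1L)] <- surf$p
  graphics::image(t(z), main = "P(SIRH) at cell centers", xlab = "x", ylab = "y")
  grDevices::dev.off()
  log_line(cfg, "report: written (severity, contingency, thresholds, surface)")
  invisible(out_path(cfg, "report.json"))
}

#' Run the full pipeline
#'
#' Executes simulate, quantify, covariates, three fits, compare and report in
#' order.
#'
#' @param cfg config list or path to a YAML config.
#' @return invisibly, the output directory.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_config(cfg)
  cfg <- validate_config(cfg)
  stage_simulate(cfg)
  stage_quantify(cfg)
  stage_covariates(cfg)
  for (m in c("glm", "gam1", "gam2")) stage_fit(cfg, m)
  stage_compare(cfg)
  stage_report(cfg)
  invisible(cfg$out_dir)
}
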