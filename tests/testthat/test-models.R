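test_that("the GLM design has exactly the specified nine columns", {
  tab <- simulate_tube_table(800, true_model(), seed = 101)
  fit <- build_model("GLM", tab)
  # intercept + 4 category dummies + distance + x + y + x*y
  expect_length(coef(fit), 9L)
  expect_error(build_model("GLM", tab[tab$landuse5 != "artificial", ]),
               "artificial")
})

test_that("contingency table reproduces printed row percentages and an exact chi-square", {
  ct <- contingency_and_chi2(TABLE1_COUNTS)
  expect_equal(unname(ct$row_pct[, "SIRH"]), c(63.2, 78.7, 58.7, 64.5, 64.6))
  expect_equal(unname(ct$row_pct[, "USIRL"]), c(36.8, 21.3, 41.3, 35.5, 35.4))
  expect_equal(ct$df, 4)
  # independent textbook recomputation: sum (O - E)^2 / E
  E <- outer(rowSums(TABLE1_COUNTS), colSums(TABLE1_COUNTS)) / sum(TABLE1_COUNTS)
  expect_equal(ct$chisq, sum((TABLE1_COUNTS - E)^2 / E), tolerance = 1e-12)
  # uniform table has no association
  expect_equal(contingency_and_chi2(matrix(10, 5, 2))$chisq, 0)
  # the data-frame interface agrees with the matrix interface
  df <- data.frame(
    y = rep(rep(1:0, 5), times = as.vector(t(TABLE1_COUNTS[, c("SIRH", "USIRL")]))),
    landuse5 = rep(rownames(TABLE1_COUNTS), times = rowSums(TABLE1_COUNTS)))
  ct2 <- contingency_and_chi2(df)
  expect_equal(ct2$chisq, ct$chisq)
})

test_that("severity summaries match the printed descriptive percentages", {
  w2016 <- data.frame(period = "2016",
                      scale = rep(c(0, 1, 2, 3), c(1542, 8, 4, 5220)))
  w2018 <- data.frame(period = "2018-2019",
                      scale = rep(c(0, 3), c(3822, 6918 - 3822)))
  sev <- severity_summary(rbind(w2016, w2018))
  expect_equal(sev$pct[sev$period == "2016" & sev$scale == 3], 77.1)
  expect_equal(sev$pct[sev$period == "2016" & sev$scale == 0], 22.8)
  expect_equal(sev$pct[sev$period == "2018-2019" & sev$scale == 0], 55.2)
  for (p in unique(sev$period))
    expect_lt(abs(sum(sev$pct[sev$period == p]) - 100), 0.2)
  expect_equal(area_share_pct(69.0, 132.17), 52.2)
})

test_that("change-flow summary tabulates transitions and the development aggregate", {
  A <- structure(list(category = c("natural", "transportation"),
                      rings = list(rifagam:::rect_ring(0, 10, 0, 10),
                                   rifagam:::rect_ring(10, 20, 0, 10))),
                 class = "landuse_layer")
  B <- structure(list(category = c("artificial", "natural"),
                      rings = A$rings), class = "landuse_layer")
  cf <- change_flow_summary(c(5, 15), c(5, 5), A, B)
  expect_equal(sum(cf$pairs$pct), 100)
  expect_equal(cf$development_related_pct, 50)
  all_dev <- change_flow_summary(c(5, 5), c(2, 8), A, B)
  expect_equal(all_dev$pairs$pct, 100)  # single natural -> artificial flow
  expect_equal(all_dev$development_related_pct, 100)
  expect_error(change_flow_summary(15, 5, A, A), "not in the change category")
  # generator calibration: ~61.6% of changed area is development-related
  b <- generate_landscape(31)
  ch <- b$landuseA$category != b$landuseB$category
  r <- b$landuseA$rects
  a <- ((r$xmax - r$xmin) * (r$ymax - r$ymin))[ch]
  dev <- b$landuseA$category[ch] == "natural" &
    b$landuseB$category[ch] %in% c("agriculture", "transportation", "artificial")
  pct <- 100 * sum(a[dev]) / sum(a)
  expect_gte(pct, 56.6)
  expect_lte(pct, 66.6)
})

test_that("distance_threshold inverts analytic curves and is monotone in the level", {
  curve <- function(d) plogis(1 - 0.01 * d)
  t1 <- distance_threshold(curve, p0 = 0.6, max_dist = 300)
  expect_equal(t1$d_star, 100 * (1 - log(1.5)), tolerance = 1e-6)
  levels <- c(0.55, 0.6, 0.65, 0.7)
  ds <- vapply(levels, function(p0)
    distance_threshold(curve, p0 = p0, max_dist = 300)$d_star, 0)
  expect_true(all(diff(ds) < 0))  # higher level -> shorter range
  t0 <- distance_threshold(function(d) plogis(-1 + 0 * d), p0 = 0.6, max_dist = 100)
  expect_equal(t0$d_star, 0)
  expect_match(t0$note, "below p0")
})

test_that("model comparison reports the AIC winner over the nested chain", {
  tab <- simulate_tube_table(2000, nonlinear_truth(), seed = 103)
  fits <- list(GLM = build_model("GLM", tab),
               GAM1 = build_model("GAM1", tab, k_dist = 8, k_spatial = 5),
               GAM2 = build_model("GAM2", tab, k_dist = 8, k_spatial = 5))
  cmp <- compare_models(fits)
  expect_equal(cmp$selected, cmp$aic$model[which.min(cmp$aic$AIC)])
  expect_equal(nrow(cmp$anova), 2L)
  expect_error(compare_models(list(A = fits$GLM,
                                   B = build_model("GLM", tab[1:500, ]))),
               "identical rows")
})

test_that("risk surfaces decompose by component and agree with point predictions", {
  b <- generate_landscape(17, extent = c(0, 2000, 0, 2000), n_patches = 16)
  g <- grid_from_extent(b$extent, 200)
  tt <- place_tubes(b, g, tubes_per_cell = 2, jitter = 10, seed = 18)
  w2 <- tt$wave2
  tab <- data.frame(
    tube_id = w2$tube_id,
    landuse5 = landuse5(w2$x, w2$y, b$landuseA, b$landuseB),
    road_dist = nearest_road_distance(w2$x, w2$y, b$roads),
    x = w2$x, y_coord = w2$y)
  set.seed(19)
  tab$y <- rbinom(nrow(tab), 1, plogis(0.4 - 0.002 * tab$road_dist))
  fit <- build_model("GAM1", tab, k_dist = 6, k_spatial = 4)
  surf <- risk_surface(fit, g, b)
  expect_equal(nrow(surf), g$n_rows * g$n_cols)
  expect_true(all(surf$p > 0 & surf$p < 1))
  lp <- qlogis(surf$p)
  expect_equal(surf$lp_landuse + surf$lp_dist + surf$lp_spatial, lp,
               tolerance = 1e-8)
  # surface values equal point predictions at the same locations
  nd <- data.frame(landuse5 = landuse5(surf$x_center, surf$y_center,
                                       b$landuseA, b$landuseB),
                   road_dist = nearest_road_distance(surf$x_center, surf$y_center,
                                                     b$roads),
                   x = surf$x_center, y_coord = surf$y_center)
  expect_equal(surf$p, predict_components(fit, nd)$p, tolerance = 1e-12)
  # an (effectively) infinitely smoothed spatial term degenerates to the
  # penalty null space: a bilinear (curvature-free) surface
  fflat <- build_model("GAM1", tab, k_dist = 6, k_spatial = 4,
                       lambda = c(1, 1e10, 1e10))
  sflat <- risk_surface(fflat, g, b)
  bilin <- lm(lp_spatial ~ x_center * y_center, sflat)
  expect_lt(max(abs(resid(bilin))), 1e-6)
})
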