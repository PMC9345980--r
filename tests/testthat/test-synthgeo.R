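small_bundle <- function(seed = 7, ...)
  generate_landscape(seed, extent = c(0, 4000, 0, 4000), n_patches = 64, ...)

test_that("landscape generation is deterministic and validates its inputs", {
  expect_identical(small_bundle(7), small_bundle(7))
  expect_false(identical(small_bundle(7), small_bundle(8)))
  expect_error(generate_landscape(1, extent = c(0, 0, 0, 100)), "degenerate")
  expect_error(small_bundle(1, change_fraction = 1.2), "change_fraction")
  expect_error(small_bundle(1, road_spacing = -5), "road_spacing")
})

test_that("land-use layers cover the extent without overlap and hit the change target", {
  b <- small_bundle(7)
  for (layer in list(b$landuseA, b$landuseB)) {
    r <- layer$rects
    area <- sum((r$xmax - r$xmin) * (r$ymax - r$ymin))
    expect_equal(area, 4000 * 4000)  # exact tiling => coverage + no overlap
  }
  # changed-area fraction measured from the layers themselves
  r <- b$landuseA$rects
  changed <- b$landuseA$category != b$landuseB$category
  frac <- sum(((r$xmax - r$xmin) * (r$ymax - r$ymin))[changed]) / (4000 * 4000)
  expect_equal(frac, b$meta$achieved_change_fraction)
  expect_gte(frac, 0.107 - 0.02)
  expect_lte(frac, 0.107 + 0.02)
  # island-sized default, tighter band stated for the calibration example
  bf <- generate_landscape(11)
  expect_gte(bf$meta$achieved_change_fraction, 0.087)
  expect_lte(bf$meta$achieved_change_fraction, 0.127)
  # no-change request gives identical layers polygon-by-polygon
  b0 <- small_bundle(7, change_fraction = 0)
  expect_identical(b0$landuseA, b0$landuseB)
})

test_that("tube placement honors counts, jitter bounds and cell membership", {
  b <- small_bundle(7)
  g <- grid_spec(0, 0, 200, 10, 10)
  t1 <- place_tubes(b, g, tubes_per_cell = 1, jitter = 20, seed = 3,
                    snap_to_road = FALSE)
  expect_equal(nrow(t1$wave1), 100)  # 10 x 10 grid fully sampled, 1 per cell
  expect_equal(nrow(t1$wave2), 100)
  t0 <- place_tubes(b, g, tubes_per_cell = 2, jitter = 0, seed = 3,
                    snap_to_road = FALSE)
  expect_equal(t0$wave1$x, t0$wave2$x)
  expect_equal(t0$wave1$y, t0$wave2$y)
  t2 <- place_tubes(b, g, tubes_per_cell = 2, jitter = 30, seed = 4,
                    snap_to_road = FALSE)
  expect_true(all(abs(t2$wave1$x - t2$wave2$x) <= 30 + 1e-9))
  expect_true(all(abs(t2$wave1$y - t2$wave2$y) <= 30 + 1e-9))
  # re-binning oracle: wave-2 tubes stay in their wave-1 cell (snapped too)
  ts <- place_tubes(b, g, tubes_per_cell = 2, jitter = 30, seed = 5)
  c1 <- cell_index(ts$wave1$x, ts$wave1$y, g)
  c2 <- cell_index(ts$wave2$x, ts$wave2$y, g)
  expect_equal(c1, c2)
  expect_error(place_tubes(b, g, tubes_per_cell = 2, jitter = 150, seed = 1),
               "jitter")
})

test_that("SIRH simulation follows the logistic truth exactly", {
  b <- small_bundle(7)
  g <- grid_from_extent(b$extent, 200)
  tt <- place_tubes(b, g, tubes_per_cell = 2, jitter = 20, seed = 8)
  w2 <- tt$wave2
  cov2 <- data.frame(landuse5 = landuse5(w2$x, w2$y, b$landuseA, b$landuseB),
                     road_dist = nearest_road_distance(w2$x, w2$y, b$roads),
                     x = w2$x, y = w2$y)
  truth <- true_model(beta0 = 0.3,
                      g_dist = function(d) -0.002 * d,
                      spatial_field = function(x, y) 0.2 * sin(x / 1000))
  cells <- simulate_sirh_labels(cov2, truth, g, seed = 9)
  # scalar re-evaluation oracle for the probability formula
  key <- paste(cell_index(w2$x, w2$y, g)$i, cell_index(w2$x, w2$y, g)$j)
  first <- !duplicated(key)
  p_oracle <- vapply(which(first), function(r) {
    eta <- 0.3 + truth$category_logodds[[as.character(cov2$landuse5[r])]] +
      (-0.002 * cov2$road_dist[r]) + 0.2 * sin(cov2$x[r] / 1000)
    1 / (1 + exp(-eta))
  }, 0)
  expect_equal(cells$p, p_oracle, tolerance = 1e-12)
  # all-zero truth: probability exactly one half everywhere
  cells0 <- simulate_sirh_labels(cov2, true_model(beta0 = 0,
    category_logodds = c(natural = 0, artificial = 0, transportation = 0,
                         agriculture = 0, change = 0)), g, seed = 1)
  expect_true(all(cells0$p == 0.5))
  expect_error(simulate_sirh_labels(w2, truth, g, seed = 1), "covariates")
})

test_that("severity pairs are drawn from the label-consistent enumerations and round-trip", {
  sirh_set <- paste(c(0, 0, 0, 1, 1, 2, 3), c(1, 2, 3, 2, 3, 3, 3))
  usirl_set <- paste(c(0, 1, 1, 2, 2, 2, 3, 3, 3), c(0, 0, 1, 0, 1, 2, 0, 1, 2))
  sev <- labels_to_severity(rep(c("SIRH", "USIRL"), each = 2000), seed = 12)
  got <- paste(sev$s1, sev$s2)
  expect_true(all(got[1:2000] %in% sirh_set))
  expect_true(all(got[2001:4000] %in% usirl_set))
  expect_setequal(got[1:2000], sirh_set)      # all 7 pairs show up
  expect_setequal(got[2001:4000], usirl_set)  # all 9 pairs show up
  expect_equal(classify_cell(sev$s1, sev$s2),
               rep(c("SIRH", "USIRL"), each = 2000))
})

test_that("empirical category odds ratio tracks the generating odds ratio", {
  # agriculture OR 2.247 vs natural, all other terms zero, n = 6918
  truth <- true_model(beta0 = 0,
                      category_logodds = c(natural = 0, artificial = 0,
                                           transportation = 0,
                                           agriculture = log(2.247), change = 0))
  lors <- vapply(1:10, function(r) {
    tab <- simulate_tube_table(6918, truth, seed = 600 + r)
    ag <- tab$landuse5 == "agriculture"; na <- tab$landuse5 == "natural"
    log((sum(tab$y[ag]) / sum(1 - tab$y[ag])) /
        (sum(tab$y[na]) / sum(1 - tab$y[na])))
  }, 0)
  expect_lt(abs(mean(lors) - log(2.247)), 0.1)
})

test_that("default truth and category mix reproduce the observed marginal SIRH rate", {
  tab <- simulate_tube_table(6918, seed = 21)
  # 4585 of 6918 tubes were SIRH (66.3%); the generator must land within 5pp
  expect_gte(mean(tab$y), 0.663 - 0.05)
  expect_lte(mean(tab$y), 0.663 + 0.05)
})
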