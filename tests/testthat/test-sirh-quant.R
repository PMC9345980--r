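test_that("cell_index uses half-open binning with closed top/right grid edge", {
  g <- grid_spec(0, 0, 200, n_rows = 2, n_cols = 2)
  expect_equal(cell_index(0, 0, g), data.frame(i = 0L, j = 0L))
  expect_equal(cell_index(200, 399.9, g), data.frame(i = 1L, j = 1L))
  expect_equal(cell_index(400, 400, g), data.frame(i = 1L, j = 1L))  # edge closed
  expect_error(cell_index(401, 10, g), "outside")
})

test_that("cell_index matches brute-force rectangle membership on random points", {
  set.seed(51)
  g <- grid_spec(-100, 50, 37.5, n_rows = 7, n_cols = 9)
  x <- runif(1000, -100, -100 + 9 * 37.5)
  y <- runif(1000, 50, 50 + 7 * 37.5)
  got <- cell_index(x, y, g)
  want <- t(mapply(oracle_cell_of, x, y, MoreArgs = list(grid = g)))
  expect_equal(got$i, unname(want[, 1]))
  expect_equal(got$j, unname(want[, 2]))
})

test_that("per-cell maximum severity follows the most-severe-tube rule", {
  g <- grid_spec(0, 0, 200, 2, 2)
  tubes <- data.frame(tube_id = c("a", "b", "c"),
                      x = c(50, 150, 250), y = c(50, 60, 250),
                      scale = c(1, 3, 2))
  m <- max_scale_per_cell(tubes, g)
  expect_equal(m$max_scale[m$i == 0 & m$j == 0], 3)  # max of {1, 3}
  expect_equal(m$max_scale[m$i == 1 & m$j == 1], 2)  # single tube
  expect_equal(nrow(m), 2)                           # unsampled cells absent
  expect_equal(nrow(max_scale_per_cell(tubes[0, ], g)), 0)
  tubes$scale[1] <- 5
  expect_error(max_scale_per_cell(tubes, g), "scale")
})

test_that("cell classification is total, exhaustive and matches the stated rules", {
  expect_equal(classify_cell(3, 3), "SIRH")    # remained at the highest level
  expect_equal(classify_cell(0, 2), "SIRH")    # increase
  expect_equal(classify_cell(3, 1), "USIRL")   # decrease
  expect_equal(classify_cell(2, 2), "USIRL")   # constant below 3
  expect_equal(classify_cell(NA, 3), "undefined")
  grid25 <- expand.grid(s1 = c(0:3, NA), s2 = c(0:3, NA))
  lab <- classify_cell(grid25$s1, grid25$s2)
  expect_equal(as.integer(table(lab)[c("SIRH", "USIRL", "undefined")]),
               c(7L, 9L, 9L))
})

test_that("tube labelling inherits cell labels, excludes undefined cells, conserves counts", {
  g <- grid_spec(0, 0, 200, 1, 2)
  w1 <- data.frame(tube_id = "p", x = 50, y = 50, scale = 1)
  w2 <- data.frame(tube_id = c("q", "r", "s"),
                   x = c(60, 120, 250), y = c(40, 90, 100),
                   period = "wave2", scale = c(3, 2, 1))
  cells <- cell_states(w1, w2, g)
  expect_equal(cells$label, c("SIRH", "undefined"))  # cell (0,1) has no wave-1 tube
  lab <- label_tubes(w2, cells, g)
  expect_equal(lab$y, c(1L, 1L))                     # both tubes in the SIRH cell
  expect_equal(attr(lab, "excluded_n"), 1L)
  expect_equal(nrow(lab) + attr(lab, "excluded_n"), nrow(w2))
})

test_that("cell labels are invariant to within-cell tube jitter", {
  set.seed(53)
  g <- grid_spec(0, 0, 200, 5, 5)
  n <- 50
  cells <- expand.grid(i = 0:4, j = 0:4)[sample(25, n, TRUE), ]
  base_x <- cells$j * 200 + runif(n, 60, 140)
  base_y <- cells$i * 200 + runif(n, 60, 140)
  mk <- function(dx, dy, scales)
    data.frame(tube_id = paste0("t", seq_len(n)), x = base_x + dx, y = base_y + dy,
               period = "w", scale = scales)
  s1 <- sample(0:3, n, TRUE); s2 <- sample(0:3, n, TRUE)
  ref <- cell_states(mk(0, 0, s1), mk(0, 0, s2), g)
  jit <- cell_states(mk(runif(n, -50, 50), runif(n, -50, 50), s1),
                     mk(runif(n, -50, 50), runif(n, -50, 50), s2), g)
  expect_equal(ref, jit)
})
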