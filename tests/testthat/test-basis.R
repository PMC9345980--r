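test_that("cubic B-spline basis: partition of unity and constant reproduction", {
  set.seed(71)
  x <- c(runif(200, 0, 10), rexp(100, 0.2))  # long right tail, like distances
  def <- bspline_basis(x, k = 10)
  B <- eval_basis(def, x)
  expect_equal(dim(B), c(300L, 10L))
  expect_equal(rowSums(B), rep(1, 300), tolerance = 1e-12)
  # residual of projecting the ones-vector onto the span
  qrB <- qr(B)
  r <- rep(1, 300) - qr.fitted(qrB, rep(1, 300))
  expect_lt(max(abs(r)), 1e-10)
  expect_error(bspline_basis(x, k = 3), "k must be")
  expect_error(bspline_basis(rep(1:3, 10), k = 8), "distinct")
})

test_that("difference penalty annihilates affine functions and only them", {
  set.seed(72)
  x <- runif(300, 0, 5)
  def <- bspline_basis(x, k = 8)
  g <- def$greville
  for (ab in list(c(0, 0), c(2, 0), c(-1, 3))) {
    cf <- ab[1] + ab[2] * g  # coefficients of an affine function of x
    expect_lt(abs(drop(crossprod(cf, def$S %*% cf))), 1e-12 * (1 + sum(cf^2)))
    # and the represented function really is affine in x
    expect_equal(drop(eval_basis(def, x) %*% cf), ab[1] + ab[2] * x,
                 tolerance = 1e-10)
  }
  cf2 <- g^2
  expect_gt(drop(crossprod(cf2, def$S %*% cf2)), 1e-6)
  ev <- eigen(def$S, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-12))        # positive semidefinite
  expect_equal(sum(ev < 1e-10), 2L)    # null space dimension exactly 2
})

test_that("basis evaluation matches the Cox-de Boor recursion oracle", {
  set.seed(73)
  x <- runif(150, 0, 20)
  def <- bspline_basis(x, k = 9)
  xs <- runif(100, def$xl + 1e-6, def$xu - 1e-6)  # strictly interior
  B <- eval_basis(def, xs)
  for (n in seq_along(xs))
    expect_equal(B[n, ], oracle_bspline_row(xs[n], def), tolerance = 1e-10)
})

test_that("tensor basis rows are outer products with bilinear penalty null space", {
  set.seed(74)
  x <- runif(200, 0, 1); y <- runif(200, -3, 3)
  tb <- tensor_basis(x, y, k_marginal = 5)
  Bx <- eval_basis(tb$def_x, x); By <- eval_basis(tb$def_y, y)
  for (n in c(1, 50, 200))
    expect_equal(tb$B[n, ], as.vector(Bx[n, ] %x% By[n, ]), tolerance = 1e-12)
  # coefficients of a + b x + c y + d x y have zero roughness in both directions
  gx <- tb$def_x$greville; gy <- tb$def_y$greville
  # column order has the y index fastest: coefficient (ix, iy) sits at
  # (ix-1)*k + iy, i.e. as.vector of the (iy, ix) matrix
  cf <- as.vector(outer(gy, gx, function(v, u) 0.5 - 2 * u + 3 * v + 1.5 * u * v))
  expect_lt(drop(crossprod(cf, tb$S_x %*% cf)), 1e-10 * sum(cf^2))
  expect_lt(drop(crossprod(cf, tb$S_y %*% cf)), 1e-10 * sum(cf^2))
  expect_equal(drop(tb$B %*% cf), 0.5 - 2 * x + 3 * y + 1.5 * x * y,
               tolerance = 1e-9)
  # separable cubic g(x)h(y) lies in the span
  f <- (1 + x - 0.5 * x^3) * (2 - y + 0.25 * y^2)
  fitcf <- qr.coef(qr(tb$B), f)
  expect_lt(max(abs(tb$B %*% fitcf - f)), 1e-8)
})

test_that("constraint absorption centers columns, drops one dimension, preserves the fit", {
  set.seed(75)
  x <- runif(400, 0, 10)
  def <- bspline_basis(x, k = 10)
  B <- eval_basis(def, x)
  con <- apply_constraints(B, list(def$S))
  expect_equal(ncol(con$X), 9L)
  expect_lt(max(abs(colSums(con$X))), 1e-9)
  expect_equal(qr(con$X)$rank, qr(B)$rank - 1L)
  # identical model span: logistic fits with and without absorption agree
  y <- rbinom(400, 1, plogis(sin(x)))
  f_raw <- glm.fit(B, y, family = binomial())
  f_con <- glm.fit(cbind(1, con$X), y, family = binomial())
  expect_equal(f_raw$fitted.values, f_con$fitted.values, tolerance = 1e-8)
})
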