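test_that("unpenalized fits match closed forms and the independent GLM oracle", {
  # grouped 2x2 data: cross-product odds ratio (40*40)/(10*10) = 16
  d <- data.frame(g = rep(c(0, 1), each = 50),
                  y = c(rep(1, 40), rep(0, 10), rep(1, 10), rep(0, 40)))
  f <- pslogit(y ~ g, d)
  expect_equal(unname(coef(f)["g"]), -log(16), tolerance = 1e-7)
  # intercept-only: logit of the mean
  f0 <- pslogit(y ~ 1, d)
  expect_equal(unname(coef(f0)), qlogis(mean(d$y)), tolerance = 1e-9)
  # multi-covariate comparison against stats::glm
  set.seed(81)
  n <- 1500
  dd <- data.frame(x1 = rnorm(n), x2 = runif(n),
                   f = factor(sample(letters[1:3], n, TRUE)))
  dd$y <- rbinom(n, 1, plogis(-0.5 + 0.7 * dd$x1 - dd$x2 + 0.4 * (dd$f == "c")))
  fit <- pslogit(y ~ x1 + x2 + f, dd)
  orc <- glm(y ~ x1 + x2 + f, binomial, dd)
  expect_equal(coef(fit), coef(orc), tolerance = 1e-6)
  expect_equal(fit$deviance, deviance(orc), tolerance = 1e-8)
  expect_equal(sqrt(diag(fit$Vb)), unname(sqrt(diag(vcov(orc)))), tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("fitted probabilities stay in (0,1); AIC identity; deviance monotone", {
  set.seed(82)
  n <- 1200
  d <- data.frame(x = runif(n, 0, 10))
  d$y <- rbinom(n, 1, plogis(1.5 * sin(d$x)))
  fit <- pslogit(y ~ s(x, k = 10), d)
  expect_true(all(fit$fitted.values > 0 & fit$fitted.values < 1))
  expect_equal(fit$aic, fit$deviance + 2 * fit$edf_total)
  expect_equal(fit$aic, AIC(fit))
  expect_true(all(diff(fit$pdev_trace) <= 1e-8))  # accepted steps never increase
  expect_true(fit$converged)
  # GCV self-consistency
  expect_equal(fit$gcv,
               fit$nobs * fit$deviance / (fit$nobs - fit$edf_total)^2)
})

test_that("infinite smoothing collapses the additive model onto the GLM", {
  set.seed(83)
  tab <- simulate_tube_table(3000, true_model(), seed = 84)
  f_glm <- build_model("GLM", tab)
  f_inf <- build_model("GAM1", tab, lambda = rep(1e10, 3))
  i_glm <- grep("landuse5", names(coef(f_glm)))
  i_inf <- grep("landuse5", names(coef(f_inf)))
  expect_equal(unname(coef(f_inf)[i_inf]), unname(coef(f_glm)[i_glm]),
               tolerance = 1e-6)
  expect_equal(fitted(f_inf), fitted(f_glm), tolerance = 1e-6)
  # smooth EDFs drop to the penalty null-space dimensions (1 and 3)
  edf <- f_inf$edf_by_block
  expect_equal(unname(edf[grep("s\\(road_dist", names(edf))]), 1, tolerance = 1e-3)
  expect_equal(unname(edf[grep("te\\(", names(edf))]), 3, tolerance = 1e-2)
})

test_that("GCV selection distinguishes linear from nonlinear effects", {
  edf_lin <- numeric(10); edf_sin <- numeric(10)
  for (r in 1:10) {
    set.seed(850 + r)
    n <- 4000
    x <- runif(n, 0, 10)
    ylin <- rbinom(n, 1, plogis(-1 + 0.3 * x))
    ysin <- rbinom(n, 1, plogis(1.8 * sin(x)))
    edf_lin[r] <- sum(pslogit(y ~ s(x, k = 10),
                              data.frame(x = x, y = ylin))$edf_by_block[2])
    edf_sin[r] <- sum(pslogit(y ~ s(x, k = 10),
                              data.frame(x = x, y = ysin))$edf_by_block[2])
  }
  expect_lte(median(edf_lin), 2.5)  # near-linear truth -> almost straight fit
  expect_gte(median(edf_sin), 4)    # oscillating truth -> clearly nonlinear fit
})

test_that("prediction reproduces training values and decomposes exactly by term", {
  set.seed(86)
  tab <- simulate_tube_table(2500, nonlinear_truth(), seed = 87)
  fit <- build_model("GAM2", tab, k_dist = 8, k_spatial = 5)
  pr <- predict_components(fit, tab)
  expect_equal(pr$p, unname(fitted(fit)), tolerance = 1e-9)
  expect_equal(pr$lp_landuse + pr$lp_dist + pr$lp_spatial, pr$lp, tolerance = 1e-10)
  tm <- predict(fit, rifagam:::add_scaled_coords(tab, fit$coord_scale),
                type = "terms")
  expect_equal(unname(rowSums(tm)), unname(fit$linear.predictors), tolerance = 1e-9)
  # unseen factor level is rejected
  bad <- tab[1:2, ]
  bad$landuse5 <- factor("wetland")
  expect_error(predict_components(fit, bad))
})

test_that("simulate() and residuals() are consistent with the fitted model", {
  set.seed(88)
  d <- data.frame(x = runif(800, 0, 6))
  d$y <- rbinom(800, 1, plogis(0.8 * d$x - 2))
  fit <- pslogit(y ~ x, d)
  sims <- simulate(fit, nsim = 200, seed = 1)
  expect_equal(dim(sims), c(800L, 200L))
  expect_lt(max(abs(rowMeans(as.matrix(sims)) - fitted(fit))), 0.2)
  rd <- residuals(fit, "deviance")
  expect_equal(sum(rd^2), fit$deviance, tolerance = 1e-8)
  expect_equal(residuals(fit, "response"), d$y - fitted(fit))
})

test_that("fixed-lambda fits validate their arguments", {
  d <- data.frame(x = runif(300), y = rbinom(300, 1, 0.5))
  expect_error(pslogit(y ~ s(x, k = 5), d, lambda = c(1, 2)), "length 1")
  expect_error(pslogit(y ~ s(x, k = 5), d, lambda = -1), ">= 0")
  d$y2 <- d$y + 1
  expect_error(pslogit(y2 ~ x, d), "binary")
})
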