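# S3 methods for fitted pslogit models.

#' @export
print.pslogit <- function(x, ...) {
  cat("Penalized-spline logistic additive model\n")
  cat("Call: ", deparse1(x$call), "\n", sep = "")
  cat(sprintf("n = %d, deviance = %.3f, total EDF = %.3f, AIC = %.3f\n",
              x$nobs, x$deviance, x$edf_total, x$aic))
  if (length(x$lambda))
    cat("smoothing parameters:", format(signif(x$lambda, 3)), "\n")
  if (!x$converged) cat("WARNING: PIRLS did not converge\n")
  invisible(x)
}

#' @export
coef.pslogit <- function(object, ...) object$coefficients

#' @export
fitted.pslogit <- function(object, ...) object$fitted.values

#' @export
formula.pslogit <- function(x, ...) x$formula

#' @export
logLik.pslogit <- function(object, ...) {
  structure(-object$deviance / 2, df = object$edf_total,
            nobs = object$nobs, class = "logLik")
}

#' @export
residuals.pslogit <- function(object,
                              type = c("deviance", "pearson", "response"),
                              ...) {
  type <- match.arg(type)
  y <- object$y; mu <- object$fitted.values
  switch(type,
    response = y - mu,
    pearson = (y - mu) / sqrt(mu * (1 - mu)),
    deviance = {
      mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
      d <- -2 * (y * log(mu) + (1 - y) * log(1 - mu))
      sign(y - mu) * sqrt(pmax(d, 0))
    })
}

#' Simulate binary responses from a fitted model
#'
#' @param object a fitted [pslogit()] model.
#' @param nsim number of response vectors.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return data frame with `nsim` simulated 0/1 response columns.
#' @export
simulate.pslogit <- function(object, nsim = 1, seed = NULL, ...) {
  expr <- quote({
    n <- object$nobs
    out <- as.data.frame(matrix(stats::rbinom(n * nsim, 1L,
                                              rep(object$fitted.values, nsim)),
                                nrow = n))
    names(out) <- paste0("sim_", seq_len(nsim))
    out
  })
  if (is.null(seed)) eval(expr) else with_seed(seed, eval(expr))
}

#' Predict from a penalized-spline logistic model
#'
#' @param object a fitted [pslogit()] model.
#' @param newdata optional data frame; omitted means the training data design.
#' @param type `"link"` (linear predictor), `"response"` (probability), or
#'   `"terms"` (matrix of per-term linear-predictor contributions, including
#'   the intercept column; rows sum to the full linear predictor).
#' @param ... unused.
#' @return numeric vector, or a matrix for `type = "terms"`.
#' @export
predict.pslogit <- function(object, newdata = NULL,
                            type = c("link", "response", "terms"), ...) {
  type <- match.arg(type)
  blocks <- object$design$blocks
  if (is.null(newdata)) {
    # rebuild from stored smooth metadata is impossible without data; keep it
    # simple: training predictions come from the stored fit
    if (type == "link") return(object$linear.predictors)
    if (type == "response") return(object$fitted.values)
    stop_fmt("type = \"terms\" requires newdata")
  }
  X <- build_design_newdata(object, newdata)
  if (type == "terms") {
    out <- vapply(blocks, function(b)
      drop(X[, b$cols, drop = FALSE] %*% object$coefficients[b$cols]),
      numeric(nrow(X)))
    if (is.null(dim(out))) out <- matrix(out, nrow = 1)
    colnames(out) <- vapply(blocks, `[[`, "", "label")
    return(out)
  }
  eta <- drop(X %*% object$coefficients)
  if (type == "response") stats::plogis(eta) else eta
}

#' Summarize a fitted pslogit model
#'
#' Produces the parametric coefficient table on the odds-ratio scale
#' (delta-method standard errors, Wald z and p) and the nonparametric table
#' of per-smooth effective degrees of freedom with truncated-rank Wald
#' chi-square tests.
#'
#' @param object a fitted [pslogit()] model.
#' @param ... unused.
#' @return object of class `summary.pslogit` with elements `parametric`
#'   (from [wald_parametric()]) and `smooth` (from [smooth_tests()]).
#' @export
summary.pslogit <- function(object, ...) {
  structure(list(call = object$call,
                 parametric = wald_parametric(object),
                 smooth = smooth_tests(object),
                 deviance = object$deviance, aic = object$aic,
                 edf_total = object$edf_total, nobs = object$nobs,
                 converged = object$converged),
            class = "summary.pslogit")
}

#' @export
print.summary.pslogit <- function(x, digits = 3, ...) {
  cat("Parametric part (odds-ratio scale)\n")
  pt <- x$parametric
  pt$p_value <- format.pval(pt$p_value, digits = digits, eps = 1e-4)
  print(format(pt, digits = digits), row.names = FALSE)
  if (nrow(x$smooth)) {
    cat("\nSmooth terms (nonparametric part)\n")
    st <- x$smooth
    st$p_value <- format.pval(st$p_value, digits = digits, eps = 1e-4)
    print(format(st, digits = digits), row.names = FALSE)
  }
  cat(sprintf("\nn = %d, deviance = %.3f, total EDF = %.3f, AIC = %.3f\n",
              x$nobs, x$deviance, x$edf_total, x$aic))
  invisible(x)
}

#' Plot fitted smooth terms
#'
#' Univariate smooths are drawn as centered partial-effect curves with
#' approximate 2-SE bands; the tensor spatial smooth as a filled contour of
#' its linear-predictor contribution.
#'
#' @param x a fitted [pslogit()] model.
#' @param which optional subset of smooth labels.
#' @param n_grid grid resolution.
#' @param ... passed to the underlying plotting calls.
#' @export
plot.pslogit <- function(x, which = NULL, n_grid = 200, ...) {
  blocks <- Filter(function(b) b$type == "smooth", x$design$blocks)
  if (!is.null(which))
    blocks <- Filter(function(b) b$label %in% which, blocks)
  for (b in blocks) {
    beta <- x$coefficients[b$cols]
    Vb <- x$Vb[b$cols, b$cols, drop = FALSE]
    if (b$kind == "s") {
      xg <- seq(b$def$xl, b$def$xu, length.out = n_grid)
      Bg <- eval_basis(b$def, xg) %*% b$Z
      f <- drop(Bg %*% beta)
      se <- sqrt(pmax(rowSums((Bg %*% Vb) * Bg), 0))
      graphics::plot(xg, f, type = "l",
                     xlab = deparse1(b$x_expr), ylab = b$label,
                     main = sprintf("%s (EDF %.2f)", b$label,
                                    x$edf_by_block[[b$label]]), ...)
      graphics::lines(xg, f + 2 * se, lty = 2)
      graphics::lines(xg, f - 2 * se, lty = 2)
    } else {
      xg <- seq(b$def$def_x$xl, b$def$def_x$xu, length.out = 60)
      yg <- seq(b$def$def_y$xl, b$def$def_y$xu, length.out = 60)
      gg <- expand.grid(x = xg, y = yg)
      Bg <- row_kronecker(eval_basis(b$def$def_x, gg$x),
                          eval_basis(b$def$def_y, gg$y)) %*% b$Z
      z <- matrix(drop(Bg %*% beta), length(xg), length(yg))
      graphics::filled.contour(xg, yg, z,
                               main = sprintf("%s (EDF %.2f)", b$label,
                                              x$edf_by_block[[b$label]]),
                               xlab = deparse1(b$x_expr),
                               ylab = deparse1(b$y_expr))
    }
  }
  invisible(x)
}

#' Analysis of deviance for nested pslogit fits
#'
#' Compares two fits on identical rows: reports the change in effective
#' degrees of freedom, the deviance chi-square test, and the F variant
#' (`F = (deviance change / EDF change) / phi` with dispersion `phi = 1`
#' for the binomial).
#'
#' @param object the smaller (nested) fit.
#' @param ... exactly one larger fit.
#' @return data frame of class `anova.pslogit`.
#' @export
anova.pslogit <- function(object, ...) {
  others <- list(...)
  others <- Filter(function(o) inherits(o, "pslogit"), others)
  if (length(others) != 1L)
    stop_fmt("anova.pslogit compares exactly two fitted models")
  anova_compare(object, others[[1]])
}

#' @rdname anova.pslogit
#' @param fit_small,fit_big nested fits (small first) on identical rows.
#' @export
anova_compare <- function(fit_small, fit_big) {
  if (fit_small$nobs != fit_big$nobs)
    stop_fmt("fits must be on identical rows (n = %d vs %d)",
             fit_small$nobs, fit_big$nobs)
  ddf <- fit_big$edf_total - fit_small$edf_total
  if (ddf <= 0)
    stop_fmt("models are not nested with an EDF increase (delta EDF = %.3f)", ddf)
  ddev <- fit_small$deviance - fit_big$deviance
  Fval <- (ddev / ddf) / 1  # binomial dispersion phi = 1
  out <- data.frame(
    delta_edf = ddf,
    delta_deviance = ddev,
    chisq_p = stats::pchisq(pmax(ddev, 0), ddf, lower.tail = FALSE),
    F_value = Fval,
    F_p = stats::pf(pmax(Fval, 0), ddf, fit_big$nobs - fit_big$edf_total,
                    lower.tail = FALSE))
  class(out) <- c("anova.pslogit", "data.frame")
  out
}
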