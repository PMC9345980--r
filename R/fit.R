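# Penalized iteratively reweighted least squares (PIRLS) for binomial-logit
# additive models, with GCV smoothing-parameter selection by coordinate-wise
# golden-section search.

#' Control settings for pslogit fitting
#'
#' @param maxit maximum PIRLS iterations.
#' @param tol relative penalized-deviance convergence tolerance.
#' @param lambda_range search box for `log10(lambda)`.
#' @param golden_tol golden-section tolerance on `log10(lambda)`.
#' @param sweeps coordinate-descent sweeps over the smoothing parameters.
#' @param ridge tiny diagonal added if the penalized normal equations are
#'   numerically singular.
#' @return list of control values.
#' @export
pslogit_control <- function(maxit = 100, tol = 1e-8,
                            lambda_range = c(-6, 6), golden_tol = 0.1,
                            sweeps = 2, ridge = 1e-8) {
  list(maxit = maxit, tol = tol, lambda_range = lambda_range,
       golden_tol = golden_tol, sweeps = sweeps, ridge = ridge)
}

binom_deviance <- function(y, mu) {
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
}

# Core fitter for fixed smoothing parameters.
pirls_fit <- function(X, y, Semb = list(), lambda = numeric(0),
                      beta_init = NULL, control = pslogit_control()) {
  n <- nrow(X); p <- ncol(X)
  if (length(lambda) != length(Semb))
    stop_fmt("lambda has length %d but there are %d penalties",
             length(lambda), length(Semb))
  if (length(lambda) && any(lambda < 0)) stop_fmt("smoothing parameters must be >= 0")
  Sl <- matrix(0, p, p)
  for (l in seq_along(Semb)) Sl <- Sl + lambda[l] * Semb[[l]]

  pen <- function(b) drop(crossprod(b, Sl %*% b))
  if (is.null(beta_init)) {
    mu <- (y + 0.5) / 2
    eta <- stats::qlogis(mu)
    beta <- NULL
    pdev <- binom_deviance(y, mu)  # no penalty yet: beta undefined
  } else {
    beta <- beta_init
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    pdev <- binom_deviance(y, mu) + pen(beta)
  }

  converged <- FALSE
  pdev_trace <- numeric(0)
  iter <- 0L
  for (it in seq_len(control$maxit)) {
    iter <- it
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    sw <- sqrt(w)
    H <- crossprod(X * sw)
    bvec <- crossprod(X, w * z)
    A <- H + Sl
    # Jacobi scaling: block scales (dummies, meters, lambda*S) differ by many
    # orders of magnitude; equilibrate before factorizing
    dsc <- sqrt(pmax(diag(A), 1e-300))
    As <- A / tcrossprod(dsc)
    R <- tryCatch(chol(As), error = function(e) chol(As + control$ridge * diag(p)))
    beta_new <- backsolve(R, forwardsolve(t(R), bvec / dsc)) / dsc
    # step-halving: never accept an increase in penalized deviance
    step <- 1
    repeat {
      beta_try <- if (is.null(beta)) beta_new else beta + step * (beta_new - beta)
      eta_try <- drop(X %*% beta_try)
      mu_try <- stats::plogis(eta_try)
      pdev_try <- binom_deviance(y, mu_try) + pen(beta_try)
      if (is.finite(pdev_try) && (pdev_try <= pdev + 1e-12 || is.null(beta) || step < 2^-30))
        break
      step <- step / 2
    }
    delta <- abs(pdev - pdev_try)
    beta <- drop(beta_try); eta <- eta_try; mu <- mu_try; pdev <- pdev_try
    pdev_trace <- c(pdev_trace, pdev)
    if (delta < control$tol * (abs(pdev) + 0.1)) { converged <- TRUE; break }
  }

  w <- pmax(mu * (1 - mu), 1e-10)
  H <- crossprod(X * sqrt(w))
  A <- H + Sl
  dsc <- sqrt(pmax(diag(A), 1e-300))
  As <- A / tcrossprod(dsc)
  R <- tryCatch(chol(As), error = function(e) chol(As + control$ridge * diag(p)))
  Vb <- chol2inv(R) / tcrossprod(dsc)
  edf <- rowSums(Vb * H)  # diag(Vb %*% H); H symmetric
  dev <- binom_deviance(y, mu)
  list(coefficients = stats::setNames(beta, colnames(X)),
       Vb = Vb, edf = edf, edf_total = sum(edf),
       deviance = dev, penalized_deviance = pdev,
       fitted.values = mu, linear.predictors = eta,
       converged = converged, iter = iter, pdev_trace = pdev_trace,
       lambda = lambda)
}

gcv_score <- function(fit, n) n * fit$deviance / (n - fit$edf_total)^2

# Coordinate-wise golden-section minimization of the GCV score over
# log10(lambda), warm-starting PIRLS from the incumbent coefficients.
select_lambdas <- function(X, y, Semb, control = pslogit_control()) {
  nl <- length(Semb)
  n <- nrow(X)
  loglam <- rep(0, nl)
  trace <- list()
  warm <- NULL
  fit_at <- function(ll) {
    f <- pirls_fit(X, y, Semb, 10^ll, beta_init = warm, control = control)
    warm <<- f$coefficients
    trace[[length(trace) + 1L]] <<- c(ll, gcv = gcv_score(f, n))
    f
  }
  best_fit <- fit_at(loglam)
  best_gcv <- gcv_score(best_fit, n)
  gr <- (sqrt(5) - 1) / 2
  lo0 <- control$lambda_range[1]; hi0 <- control$lambda_range[2]
  for (sweep in seq_len(control$sweeps)) {
    for (l in seq_len(nl)) {
      g <- function(v) {
        ll <- loglam; ll[l] <- v
        f <- fit_at(ll)
        list(gcv = gcv_score(f, n), fit = f)
      }
      lo <- lo0; hi <- hi0
      x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
      f1 <- g(x1); f2 <- g(x2)
      evals <- list(c(x1, f1$gcv), c(x2, f2$gcv))
      while (hi - lo > control$golden_tol) {
        if (f1$gcv <= f2$gcv) {
          hi <- x2; x2 <- x1; f2 <- f1
          x1 <- hi - gr * (hi - lo); f1 <- g(x1)
          evals[[length(evals) + 1L]] <- c(x1, f1$gcv)
        } else {
          lo <- x1; x1 <- x2; f1 <- f2
          x2 <- lo + gr * (hi - lo); f2 <- g(x2)
          evals[[length(evals) + 1L]] <- c(x2, f2$gcv)
        }
      }
      gv <- vapply(evals, `[`, 0, 2)
      if (max(gv) - min(gv) < 1e-8 * (abs(mean(gv)) + 1e-12)) {
        # flat objective: take the smallest lambda in the box
        message(sprintf("GCV flat in smoothing parameter %d; using lambda = 1e%g",
                        l, lo0))
        cand <- g(lo0)
      } else {
        cand <- if (f1$gcv <= f2$gcv) f1 else f2
      }
      v <- cand$fit$lambda
      if (cand$gcv <= best_gcv + 1e-12) {
        loglam[l] <- log10(v[l])
        best_gcv <- cand$gcv
        best_fit <- cand$fit
      }
    }
  }
  # refit at the selected point from the best coefficients (tight convergence)
  final <- pirls_fit(X, y, Semb, 10^loglam,
                     beta_init = best_fit$coefficients, control = control)
  list(fit = final, loglam = loglam,
       gcv = gcv_score(final, n),
       trace = do.call(rbind, trace))
}

#' Fit a penalized-spline logistic additive model
#'
#' Fits `logit P(y = 1) = parametric terms + penalized smooths` by penalized
#' IRLS.  Smooth terms are declared with [s()] (cubic B-spline with
#' second-order difference penalty; `by =` gives factor-by smooths) and
#' [te()] (tensor-product spatial smooth with one smoothing parameter per
#' direction).  With `lambda = NULL` the smoothing parameters minimize the
#' GCV score `n * D / (n - EDF)^2` by coordinate-wise golden-section search
#' on `log10(lambda)`; a numeric `lambda` fixes them.  A model with no smooth
#' terms is an unpenalized logistic GLM.
#'
#' @param formula model formula; response must be binary 0/1.
#' @param data data frame.
#' @param lambda optional fixed smoothing-parameter vector (one per penalty:
#'   each `s()` smooth has one, each factor-by level one, each `te()` two).
#' @param control a [pslogit_control()] list.
#' @return an object of class `pslogit`: coefficients, Bayesian covariance
#'   `Vb`, per-term effective degrees of freedom, deviance, AIC
#'   (`deviance + 2 * EDF`), fitted probabilities, smoothing parameters,
#'   convergence information, and the design metadata needed by
#'   [predict.pslogit()].
#' @seealso [summary.pslogit()], [anova.pslogit()], [predict.pslogit()]
#' @export
pslogit <- function(formula, data, lambda = NULL,
                    control = pslogit_control()) {
  cl <- match.call()
  if (!is.data.frame(data)) data <- as.data.frame(data)
  des <- build_design(formula, data)
  n <- nrow(des$X)

  if (des$n_lambda == 0L) {
    core <- pirls_fit(des$X, des$y, list(), numeric(0), control = control)
    loglam <- numeric(0); gcv <- gcv_score(core, n); gcv_trace <- NULL
  } else if (!is.null(lambda)) {
    if (length(lambda) != des$n_lambda)
      stop_fmt("lambda must have length %d (one per penalty)", des$n_lambda)
    core <- pirls_fit(des$X, des$y, des$Semb, lambda, control = control)
    loglam <- log10(pmax(lambda, 1e-300)); gcv <- gcv_score(core, n); gcv_trace <- NULL
  } else {
    sel <- select_lambdas(des$X, des$y, des$Semb, control)
    core <- sel$fit; loglam <- sel$loglam; gcv <- sel$gcv; gcv_trace <- sel$trace
  }
  if (!core$converged)
    warning("PIRLS did not converge in ", control$maxit,
            " iterations; results are the last accepted step")

  blocks <- des$blocks
  edf_by_block <- vapply(blocks, function(b) sum(core$edf[b$cols]), 0)
  names(edf_by_block) <- vapply(blocks, `[[`, "", "label")

  fit <- structure(list(
    coefficients = core$coefficients,
    Vb = core$Vb,
    edf = core$edf,
    edf_by_block = edf_by_block,
    edf_total = core$edf_total,
    deviance = core$deviance,
    null.deviance = binom_deviance(des$y, mean(des$y)),
    aic = core$deviance + 2 * core$edf_total,
    fitted.values = core$fitted.values,
    linear.predictors = core$linear.predictors,
    lambda = if (des$n_lambda) 10^loglam else numeric(0),
    gcv = gcv, gcv_trace = gcv_trace,
    converged = core$converged, iter = core$iter,
    pdev_trace = core$pdev_trace,
    y = des$y, nobs = n,
    design = list(blocks = blocks, terms_par = des$terms_par,
                  xlevels = des$xlevels, n_lambda = des$n_lambda),
    formula = formula, call = cl
  ), class = "pslogit")
  fit
}
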