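# Formula interface: parametric terms plus s() / te() smooth terms are
# assembled into a block-structured design with per-block penalties.

#' Specify a univariate penalized smooth in a pslogit formula
#'
#' Used inside [pslogit()] formulas, e.g. `y ~ f + s(d, k = 10, by = f)`.
#' With `by` a factor, one centered smooth of `x` is built per level, each
#' with its own smoothing parameter (a factor-by smooth: the varying-
#' coefficient construction used for distance-by-land-use interactions).
#'
#' @param x covariate.
#' @param k basis dimension (cubic B-spline, second-order difference penalty).
#' @param by optional factor: one smooth per level.
#' @return smooth specification (internal use).
#' @export
s <- function(x, k = 10, by = NULL) {
  structure(list(type = "s", x = x, k = k, by = by), class = "ps_smooth_input")
}

#' Specify a tensor-product spatial smooth in a pslogit formula
#'
#' @param x,y paired coordinates.
#' @param k marginal basis dimension (the term has `k^2` coefficients and two
#'   smoothing parameters, one per direction).
#' @return smooth specification (internal use).
#' @export
te <- function(x, y, k = 6) {
  structure(list(type = "te", x = x, y = y, k = k), class = "ps_smooth_input")
}

# Usable basis dimension for a smooth: shrink towards the number of distinct
# covariate values; with fewer than 4 distinct values no spline is possible
# (error for a plain smooth; for a factor-by level the smooth is dropped with
# a message, e.g. road-snapped transportation tubes all at distance 0).
smooth_k <- function(x, k, label, required = TRUE) {
  nd <- length(unique(x[is.finite(x)]))
  if (nd < 4) {
    if (required)
      stop_fmt("smooth '%s': need at least 4 distinct covariate values, got %d",
               label, nd)
    message(sprintf(
      "smooth '%s' dropped: only %d distinct covariate value(s) in this level",
      label, nd))
    return(NA_integer_)
  }
  if (nd < k)
    message(sprintf("smooth '%s': basis dimension reduced from %d to %d distinct values",
                    label, k, nd))
  min(k, nd)
}

# Build the block design for a pslogit formula.
# Returns list(X, y, blocks, n_lambda, Semb (embedded p x p penalties),
#              terms_par, xlevels).
build_design <- function(formula, data) {
  tf <- stats::terms(formula, data = data)
  labels <- attr(tf, "term.labels")
  is_sp <- grepl("^(s|te)\\(", labels)
  y <- eval(formula[[2]], data, environment(formula))
  if (!all(y %in% 0:1)) stop_fmt("response must be binary 0/1")
  y <- as.numeric(y)

  ns <- asNamespace("rifagam")
  par_formula <- if (any(!is_sp)) stats::reformulate(labels[!is_sp], intercept = TRUE)
                 else ~1
  environment(par_formula) <- environment(formula)
  mf <- stats::model.frame(par_formula, data)
  terms_par <- attr(mf, "terms")
  Xp <- stats::model.matrix(terms_par, mf)
  xlevels <- stats::.getXlevels(terms_par, mf)

  blocks <- list()
  # one parametric block per term (intercept = assign 0) so predict() can
  # report per-term linear-predictor contributions
  asg <- attr(Xp, "assign")
  for (a in unique(asg)) {
    cols <- which(asg == a)
    lab <- if (a == 0) "(Intercept)" else labels[!is_sp][a]
    blocks[[length(blocks) + 1L]] <- list(
      label = lab, type = "parametric", X = Xp[, cols, drop = FALSE],
      penalties = list(), lambda_idx = integer(0))
  }

  n_lambda <- 0L
  for (lab in labels[is_sp]) {
    expr <- str2lang(lab)
    obj <- eval(expr, data, ns)
    fn <- as.character(expr[[1]])
    mc <- match.call(get(fn, envir = ns), expr)
    if (obj$type == "s") {
      if (is.null(obj$by)) {
        k_eff <- smooth_k(obj$x, obj$k, lab, required = TRUE)
        def <- bspline_basis(obj$x, k_eff)
        con <- apply_constraints(eval_basis(def, obj$x), list(def$S))
        n_lambda <- n_lambda + 1L
        blocks[[length(blocks) + 1L]] <- list(
          label = lab, type = "smooth", kind = "s",
          X = con$X, penalties = con$S, lambda_idx = n_lambda,
          def = def, Z = con$Z, x_expr = mc$x, by_expr = NULL, by_level = NULL)
      } else {
        byf <- as.factor(obj$by)
        for (lv in levels(byf)) {
          rows <- which(byf == lv)
          if (length(rows) == 0L)
            stop_fmt("factor-by smooth: level '%s' has no observations", lv)
          lv_lab <- sprintf("s(%s):%s", deparse1(mc$x), lv)
          k_eff <- smooth_k(obj$x[rows], obj$k, lv_lab, required = FALSE)
          if (is.na(k_eff)) next  # level carries no usable covariate variation
          def <- bspline_basis(obj$x[rows], k_eff)
          B <- matrix(0, length(obj$x), k_eff)
          B[rows, ] <- eval_basis(def, obj$x[rows])
          con <- apply_constraints(B, list(def$S))
          n_lambda <- n_lambda + 1L
          blocks[[length(blocks) + 1L]] <- list(
            label = lv_lab, type = "smooth", kind = "s",
            X = con$X, penalties = con$S, lambda_idx = n_lambda,
            def = def, Z = con$Z,
            x_expr = mc$x, by_expr = mc$by, by_level = lv)
        }
      }
    } else {
      tb <- tensor_basis(obj$x, obj$y, obj$k)
      con <- apply_constraints(tb$B, list(tb$S_x, tb$S_y))
      blocks[[length(blocks) + 1L]] <- list(
        label = lab, type = "smooth", kind = "te",
        X = con$X, penalties = con$S,
        lambda_idx = n_lambda + 1:2,
        def = list(def_x = tb$def_x, def_y = tb$def_y, k = obj$k),
        Z = con$Z, x_expr = mc$x, y_expr = mc$y,
        by_expr = NULL, by_level = NULL)
      n_lambda <- n_lambda + 2L
    }
  }

  # assemble
  p <- 0L
  for (b in seq_along(blocks)) {
    nb <- ncol(blocks[[b]]$X)
    blocks[[b]]$cols <- p + seq_len(nb)
    p <- p + nb
  }
  X <- do.call(cbind, lapply(blocks, `[[`, "X"))
  colnames(X) <- unlist(lapply(blocks, function(b) {
    cn <- colnames(b$X)
    if (is.null(cn)) paste0(b$label, ".", seq_len(ncol(b$X))) else cn
  }))
  Semb <- vector("list", n_lambda)
  for (b in blocks) {
    for (q in seq_along(b$penalties)) {
      S <- matrix(0, p, p)
      S[b$cols, b$cols] <- b$penalties[[q]]
      Semb[[b$lambda_idx[q]]] <- S
    }
  }
  # drop the heavy per-block X copies; keep structure for prediction
  blocks <- lapply(blocks, function(b) { b$X <- NULL; b })
  list(X = X, y = y, blocks = blocks, n_lambda = n_lambda, Semb = Semb,
       terms_par = terms_par, xlevels = xlevels)
}

# Rebuild the design matrix for new data, using stored bases/constraints.
build_design_newdata <- function(object, newdata) {
  ns <- asNamespace("rifagam")
  tp <- stats::delete.response(object$design$terms_par)
  mf <- stats::model.frame(tp, newdata, xlev = object$design$xlevels,
                           na.action = stats::na.fail)
  Xp <- stats::model.matrix(tp, mf)
  asg <- attr(Xp, "assign")
  n <- nrow(newdata)
  out <- vector("list", length(object$design$blocks))
  pi <- 0L
  for (k in seq_along(object$design$blocks)) {
    b <- object$design$blocks[[k]]
    if (b$type == "parametric") {
      pi <- pi + 1L
      a <- unique(asg)[pi]
      out[[k]] <- Xp[, asg == a, drop = FALSE]
    } else if (b$kind == "s") {
      xv <- eval(b$x_expr, newdata, ns)
      B <- eval_basis(b$def, xv)
      if (!is.null(b$by_expr)) {
        byv <- as.factor(eval(b$by_expr, newdata, ns))
        B[byv != b$by_level, ] <- 0
      }
      out[[k]] <- B %*% b$Z
    } else {
      xv <- eval(b$x_expr, newdata, ns)
      yv <- eval(b$y_expr, newdata, ns)
      B <- row_kronecker(eval_basis(b$def$def_x, xv),
                         eval_basis(b$def$def_y, yv))
      out[[k]] <- B %*% b$Z
    }
  }
  do.call(cbind, out)
}
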