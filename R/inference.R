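# Wald inference: parametric odds-ratio table and truncated-rank chi-square
# tests for penalized smooth terms.

#' Parametric Wald table on the odds-ratio scale
#'
#' For each parametric coefficient reports the odds ratio `exp(beta)`, the
#' delta-method standard error on the OR scale (`OR * SE(beta)`), the Wald
#' statistic `z = beta / SE(beta)` and its two-sided normal p-value.
#'
#' @param fit a converged [pslogit()] fit.
#' @return data frame `term, odds_ratio, se_or, z_value, p_value, estimate,
#'   se_beta`.
#' @export
wald_parametric <- function(fit) {
  idx <- unlist(lapply(fit$design$blocks,
                       function(b) if (b$type == "parametric") b$cols))
  beta <- fit$coefficients[idx]
  se <- sqrt(diag(fit$Vb)[idx])
  z <- beta / se
  data.frame(term = names(beta),
             odds_ratio = exp(beta),
             se_or = exp(beta) * se,
             z_value = z,
             p_value = 2 * stats::pnorm(-abs(z)),
             estimate = beta,
             se_beta = se,
             row.names = NULL)
}

#' Wald chi-square tests for smooth terms
#'
#' For each smooth block computes `chisq = b' V^- b` where `V^-` is the
#' pseudo-inverse of the term's coefficient covariance truncated at rank
#' `round(EDF)`, with a chi-square reference on `round(EDF)` degrees of
#' freedom.  Terms with EDF below 0.5 are skipped with a notice (their test
#' statistic is reported as `NA`).
#'
#' @param fit a converged [pslogit()] fit.
#' @return data frame `term, edf, chisq, df, p_value`, one row per smooth.
#' @export
smooth_tests <- function(fit) {
  sm <- Filter(function(b) b$type == "smooth", fit$design$blocks)
  if (!length(sm))
    return(data.frame(term = character(0), edf = numeric(0),
                      chisq = numeric(0), df = integer(0),
                      p_value = numeric(0)))
  out <- data.frame(term = vapply(sm, `[[`, "", "label"),
                    edf = NA_real_, chisq = NA_real_, df = NA_integer_,
                    p_value = NA_real_)
  for (k in seq_along(sm)) {
    b <- sm[[k]]
    edf <- sum(fit$edf[b$cols])
    out$edf[k] <- edf
    if (edf < 0.5) {
      message(sprintf("smooth term '%s': EDF %.3f < 0.5, test skipped", b$label, edf))
      next
    }
    r <- max(1L, as.integer(round(edf)))
    bt <- fit$coefficients[b$cols]
    Vt <- fit$Vb[b$cols, b$cols, drop = FALSE]
    eg <- eigen((Vt + t(Vt)) / 2, symmetric = TRUE)
    r <- min(r, sum(eg$values > max(eg$values) * 1e-10))
    U <- eg$vectors[, seq_len(r), drop = FALSE]
    Vinv <- U %*% (t(U) / eg$values[seq_len(r)])
    stat <- drop(crossprod(bt, Vinv %*% bt))
    out$chisq[k] <- stat
    out$df[k] <- r
    out$p_value[k] <- stats::pchisq(stat, r, lower.tail = FALSE)
  }
  out
}
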