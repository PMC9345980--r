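#' @keywords internal
"_PACKAGE"

# Round half away from zero at `digits` decimals (table-formatting convention;
# base round() uses round-half-even).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_fmt("'%s' must be a single finite number", name)
  if (x < lower || x > upper)
    stop_fmt("'%s' must be in [%g, %g], got %g", name, lower, upper, x)
  invisible(x)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so seeded helpers do not perturb outer simulations.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Land-use category vocabulary.  `natural` is the model reference level; the
# four base categories come from the land-use layers, `change` is the overlay
# level assigned where the two reference years disagree.
LU4 <- c("natural", "artificial", "transportation", "agriculture")
LU5 <- c("natural", "artificial", "transportation", "agriculture", "change")

landuse5_factor <- function(x) factor(x, levels = LU5)
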