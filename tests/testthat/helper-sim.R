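# Shared simulation scenarios for the study-condition tests.

# Category-specific nonlinear distance effects plus a smooth spatial bump:
# transportation decays steeply with road distance, land-use-change areas
# have a non-monotone mid-range elevation, the other categories are flat.
nonlinear_truth <- function() {
  true_model(
    beta0 = log(1.547),
    g_dist = list(
      transportation = function(d) 1.6 * exp(-d / 150) - 0.4,
      change = function(d) 1.2 * sin(pi * d / 400)
    ),
    spatial_field = function(x, y)
      1.0 * exp(-((x - 3000)^2 + (y - 8500)^2) / (2 * 2500^2))
  )
}

# Truth whose transportation distance-probability curve crosses 0.6 exactly
# at 350 m: logit p = 1.6 - (1.6 - logit(0.6)) / 350 * d for transportation.
threshold_truth <- function() {
  slope <- (stats::qlogis(0.6) - 1.6) / 350
  true_model(
    beta0 = log(1.547),
    category_logodds = c(natural = 0,
                         artificial = log(1.251),
                         transportation = 1.6 - log(1.547),
                         agriculture = log(2.247),
                         change = log(1.354)),
    g_dist = list(transportation = function(d) slope * d)
  )
}

TRUE_ORS <- c(agriculture = 2.247, transportation = 1.346,
              change = 1.354, artificial = 1.251)

or_from_fit <- function(fit) {
  w <- wald_parametric(fit)
  or <- w$odds_ratio
  names(or) <- sub("^landuse5", "", w$term)
  or[names(TRUE_ORS)]
}
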