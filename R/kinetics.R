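#' Michaelis-Menten initial velocity
#'
#' `v = vmax * s / (km_app + s)`.
#'
#' @param vmax Maximum velocity, rate units, > 0.
#' @param km_app_mM Apparent Michaelis constant, mM, > 0.
#' @param s_mM Substrate concentration, mM, > 0.
#' @return Initial velocity, same units as `vmax`. Vectorized over `s_mM`.
#' @export
michaelis_menten_velocity <- function(vmax, km_app_mM, s_mM) {
  stopifnot_number(vmax, "vmax", positive = TRUE)
  stopifnot_number(km_app_mM, "km_app_mM", positive = TRUE)
  stopifnot_number(s_mM, "s_mM", positive = TRUE)
  vmax * s_mM / (km_app_mM + s_mM)
}

#' Apparent Km under competitive inhibition
#'
#' `Km_app = Km * (1 + [I]/Ki)`: the substrate must out-compete the inhibitor,
#' raising the apparent Michaelis constant linearly in inhibitor
#' concentration while Vmax is untouched.
#'
#' @param km_mM Uninhibited Michaelis constant, mM, > 0.
#' @param i_uM Inhibitor concentration, uM, >= 0. Vectorized.
#' @param ki_uM Inhibition constant, uM, > 0.
#' @return Apparent Km, mM.
#' @export
km_app <- function(km_mM, i_uM, ki_uM) {
  stopifnot_number(km_mM, "km_mM", positive = TRUE)
  stopifnot_number(i_uM, "i_uM", nonnegative = TRUE)
  stopifnot_number(ki_uM, "ki_uM", positive = TRUE)
  km_mM * (1 + i_uM / ki_uM)
}

#' Velocity dataset over a substrate x inhibitor grid
#'
#' @param inhibitor_uM Inhibitor concentrations, uM (>= 2 values, must
#'   include 0).
#' @param substrate_mM Substrate concentrations, mM, all > 0 (>= 3 values).
#' @param v Velocity matrix, one row per inhibitor concentration, one column
#'   per substrate concentration; all > 0.
#' @return A `velocity_dataset` object.
#' @export
velocity_dataset <- function(inhibitor_uM, substrate_mM, v) {
  stopifnot_number(inhibitor_uM, "inhibitor_uM", nonnegative = TRUE)
  stopifnot_number(substrate_mM, "substrate_mM", positive = TRUE)
  v <- as.matrix(v)
  if (length(substrate_mM) < 3) {
    ec_stop("insufficient_data", "need >= 3 substrate concentrations")
  }
  if (length(inhibitor_uM) < 2 || !any(inhibitor_uM == 0)) {
    ec_stop("insufficient_data",
            "need >= 2 inhibitor concentrations including 0")
  }
  if (nrow(v) != length(inhibitor_uM) || ncol(v) != length(substrate_mM)) {
    ec_stop("domain_error", "velocity matrix dimensions do not match grids")
  }
  stopifnot_number(c(v), "v", positive = TRUE)
  ord_i <- order(inhibitor_uM)
  ord_s <- order(substrate_mM)
  structure(list(inhibitor_uM = inhibitor_uM[ord_i],
                 substrate_mM = substrate_mM[ord_s],
                 v = v[ord_i, ord_s, drop = FALSE]),
            class = "velocity_dataset")
}

#' @export
print.velocity_dataset <- function(x, ...) {
  cat(sprintf("<velocity_dataset> %d inhibitor x %d substrate levels (I: %s uM)\n",
              length(x$inhibitor_uM), length(x$substrate_mM),
              paste(x$inhibitor_uM, collapse = ", ")))
  invisible(x)
}

#' Lineweaver-Burk double-reciprocal fit
#'
#' Ordinary least squares of `1/v` on `1/s`. `Vmax = 1/intercept`,
#' `Km_app = slope/intercept`. Unweighted OLS in reciprocal space is used
#' deliberately (the classical presentation); a direct nonlinear
#' Michaelis-Menten fit serves only as a cross-check in the test suite.
#'
#' @param s_mM Substrate concentrations, mM, >= 3 values.
#' @param v Initial velocities, > 0, same length.
#' @param inhibitor_uM Optional inhibitor concentration annotation, uM.
#' @return A `kinetic_fit` list: `inhibitor_uM`, `slope`, `intercept`,
#'   `km_app_mM`, `vmax`, `r2`.
#' @export
lineweaver_burk_fit <- function(s_mM, v, inhibitor_uM = NA_real_) {
  stopifnot_number(s_mM, "s_mM", positive = TRUE)
  stopifnot_number(v, "v", positive = TRUE)
  if (length(s_mM) < 3 || length(v) < 3) {
    ec_stop("insufficient_data", "need >= 3 (substrate, velocity) points")
  }
  if (length(s_mM) != length(v)) {
    ec_stop("domain_error", "s_mM and v lengths differ")
  }
  x <- 1 / s_mM
  y <- 1 / v
  if (stats::var(y) == 0) {
    # zero-order regime: v saturated at all tested s
    ec_warn("degenerate_data",
            "constant velocity across substrate levels; Km_app ~ 0")
    return(structure(list(inhibitor_uM = inhibitor_uM, slope = 0,
                          intercept = y[1], km_app_mM = 0, vmax = v[1],
                          r2 = NA_real_),
                     class = "kinetic_fit"))
  }
  fit <- stats::lm(y ~ x)
  intercept <- unname(stats::coef(fit)[1])
  slope <- unname(stats::coef(fit)[2])
  if (intercept <= 0) {
    ec_stop("non_saturating_data",
            "double-reciprocal intercept <= 0: data do not saturate")
  }
  structure(list(inhibitor_uM = inhibitor_uM, slope = slope,
                 intercept = intercept, km_app_mM = slope / intercept,
                 vmax = 1 / intercept,
                 r2 = suppressWarnings(summary(fit)$r.squared)),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit> [I] = %g uM: Km_app = %.4g mM, Vmax = %.4g (r2 %.4g)\n",
              x$inhibitor_uM, x$km_app_mM, x$vmax, x$r2))
  invisible(x)
}

#' Inhibition constant from the Km_app-vs-[I] secondary replot
#'
#' Fits `Km_app = Km + (Km/Ki) * [I]` by ordinary least squares:
#' `Km` is the intercept, and `Ki = intercept/slope`.
#'
#' @param i_uM Inhibitor concentrations, uM (>= 2 distinct values).
#' @param km_app_mM Apparent Km at each concentration, mM, > 0.
#' @return A `ki_result` list: `ki_uM`, `km_mM`, `replot_slope`, `r2`,
#'   `mode` (unset, `NA`).
#' @export
ki_from_replot <- function(i_uM, km_app_mM) {
  stopifnot_number(i_uM, "i_uM", nonnegative = TRUE)
  stopifnot_number(km_app_mM, "km_app_mM", positive = TRUE)
  if (length(unique(i_uM)) < 2) {
    ec_stop("insufficient_data", "need >= 2 distinct inhibitor concentrations")
  }
  fit <- stats::lm(km_app_mM ~ i_uM)
  intercept <- unname(stats::coef(fit)[1])
  slope <- unname(stats::coef(fit)[2])
  if (slope <= 0) {
    ec_stop("no_inhibition",
            "replot slope <= 0: Km_app does not increase with [I]; Ki undefined")
  }
  if (intercept <= 0) {
    ec_stop("invalid_replot", "replot intercept <= 0: no positive Km estimate")
  }
  r2 <- if (length(i_uM) > 2) {
    suppressWarnings(summary(fit)$r.squared)
  } else {
    NA_real_
  }
  structure(list(ki_uM = intercept / slope, km_mM = intercept,
                 replot_slope = slope, r2 = r2, mode = NA_character_),
            class = "ki_result")
}

#' @export
print.ki_result <- function(x, ...) {
  cat(sprintf("<ki_result> Ki = %.4g uM, Km = %.4g mM, mode = %s\n",
              x$ki_uM, x$km_mM, x$mode))
  invisible(x)
}

# total relative change across an ordered series
rel_spread <- function(x) (max(x) - min(x)) / mean(x)

# strictly monotone AND total relative change exceeds tau
strictly_up <- function(x, tau) all(diff(x) > 0) && (x[length(x)] - x[1]) / x[1] > tau
strictly_down <- function(x, tau) all(diff(x) < 0) && (x[1] - x[length(x)]) / x[1] > tau

#' Classify the inhibition mode from per-inhibitor kinetic fits
#'
#' Competitive: Vmax constant (relative spread < `tau_v`) while Km_app rises;
#' noncompetitive: Km_app constant while Vmax falls; uncompetitive: both fall;
#' anything else is mixed. "Rises"/"falls" means strictly monotone with total
#' relative change > tau.
#'
#' @param fits List of `kinetic_fit` objects ordered by increasing
#'   inhibitor concentration.
#' @param tau_v,tau_k Relative-spread tolerances (default 0.10 each).
#' @return One of `"competitive"`, `"noncompetitive"`, `"uncompetitive"`,
#'   `"mixed"`.
#' @export
classify_inhibition_mode <- function(fits, tau_v = 0.10, tau_k = 0.10) {
  if (length(fits) < 2) {
    ec_stop("insufficient_data", "need >= 2 per-inhibitor fits")
  }
  i <- vapply(fits, function(f) f$inhibitor_uM, numeric(1))
  if (is.unsorted(i, strictly = TRUE)) {
    ec_stop("domain_error", "fits must be ordered by increasing inhibitor_uM")
  }
  km <- vapply(fits, function(f) f$km_app_mM, numeric(1))
  vm <- vapply(fits, function(f) f$vmax, numeric(1))
  if (rel_spread(vm) < tau_v && strictly_up(km, tau_k)) return("competitive")
  if (rel_spread(km) < tau_k && strictly_down(vm, tau_v)) return("noncompetitive")
  if (strictly_down(km, tau_k) && strictly_down(vm, tau_v)) return("uncompetitive")
  "mixed"
}

#' Full kinetic analysis of a velocity dataset
#'
#' Runs a Lineweaver-Burk fit per inhibitor concentration, classifies the
#' inhibition mode, and extracts Ki from the Km_app-vs-[I] secondary replot.
#'
#' @param vds A [velocity_dataset()].
#' @param tau_v,tau_k Mode-classification tolerances, see
#'   [classify_inhibition_mode()].
#' @return A `ki_result` with `mode` set and a `per_inhibitor` list of
#'   `kinetic_fit` objects attached.
#' @export
analyze_kinetics <- function(vds, tau_v = 0.10, tau_k = 0.10) {
  if (!inherits(vds, "velocity_dataset")) {
    ec_stop("domain_error", "`vds` must be a velocity_dataset")
  }
  fits <- lapply(seq_along(vds$inhibitor_uM), function(k) {
    lineweaver_burk_fit(vds$substrate_mM, vds$v[k, ],
                        inhibitor_uM = vds$inhibitor_uM[k])
  })
  mode <- classify_inhibition_mode(fits, tau_v = tau_v, tau_k = tau_k)
  res <- ki_from_replot(vds$inhibitor_uM,
                        vapply(fits, function(f) f$km_app_mM, numeric(1)))
  res$mode <- mode
  res$per_inhibitor <- fits
  res
}
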