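#' Fluorescence titration at fixed total protein
#'
#' An ordered ligand-concentration series with measured emission intensities
#' at one temperature. Exactly one point must have `dt_M = 0`; its intensity
#' defines F0 (the unquenched baseline). Points with F >= F0 at dt > 0 are
#' retained but flagged: they carry no quenching information and are excluded
#' by [quench_transform()].
#'
#' @param temperature_K Absolute temperature, K.
#' @param pt_M Total protein concentration, mol/L (assay default 4.6e-8,
#'   i.e. 46 nM).
#' @param dt_M Total ligand concentrations, mol/L, strictly increasing,
#'   including 0.
#' @param intensity Fluorescence intensities, > 0, same length as `dt_M`.
#' @param excitation_nm,emission_peak_nm Optional metadata (defaults 280, 340).
#' @return A `fluor_titration` object.
#' @export
fluor_titration <- function(temperature_K, pt_M, dt_M, intensity,
                            excitation_nm = 280, emission_peak_nm = 340) {
  stopifnot_number(temperature_K, "temperature_K", positive = TRUE)
  stopifnot_number(pt_M, "pt_M", positive = TRUE)
  stopifnot_number(dt_M, "dt_M", nonnegative = TRUE)
  stopifnot_number(intensity, "intensity", positive = TRUE)
  if (length(dt_M) != length(intensity)) {
    ec_stop("domain_error", "dt_M and intensity lengths differ")
  }
  if (sum(dt_M == 0) != 1) {
    ec_stop("missing_baseline", "exactly one point must have dt_M = 0 (F0)")
  }
  if (is.unsorted(dt_M, strictly = TRUE)) {
    ec_stop("domain_error", "dt_M must be strictly increasing")
  }
  f0 <- intensity[dt_M == 0]
  n_rising <- sum(intensity[dt_M > 0] >= f0)
  if (n_rising > 0) {
    ec_warn("non_quenching_points",
            sprintf("%d point(s) with F >= F0; flagged for exclusion", n_rising))
  }
  structure(list(temperature_K = temperature_K, pt_M = pt_M,
                 dt_M = dt_M, intensity = intensity, f0 = f0,
                 excitation_nm = excitation_nm,
                 emission_peak_nm = emission_peak_nm),
            class = "fluor_titration")
}

#' @export
print.fluor_titration <- function(x, ...) {
  cat(sprintf("<fluor_titration> %g K, Pt = %.3g M, %d points, dt up to %.3g M\n",
              x$temperature_K, x$pt_M, length(x$dt_M), max(x$dt_M)))
  invisible(x)
}

#' Static-quench linearizing transform
#'
#' Maps each titration point with `dt > 0` to the coordinates of the
#' linearized binding plot: `x = dt * F0 / (F0 - F)` and `y = F0 / F`.
#' Under the ground-state complexation mass balance these satisfy
#' `y = KA * x - n * KA * Pt` exactly, so the association constant is the
#' slope and the site number comes from the intercept. Points with
#' `F >= F0` are excluded (no quenching signal, x undefined).
#'
#' @param t A [fluor_titration()].
#' @return Data frame with columns `dt_M`, `x`, `y`; attribute
#'   `excluded` holds the dt values of excluded points.
#' @export
quench_transform <- function(t) {
  if (!inherits(t, "fluor_titration")) {
    ec_stop("domain_error", "`t` must be a fluor_titration")
  }
  f0 <- t$f0
  keep <- t$dt_M > 0 & t$intensity < f0
  excluded <- t$dt_M[t$dt_M > 0 & t$intensity >= f0]
  if (!any(keep)) {
    ec_stop("no_quenching", "no points with F < F0: nothing to fit")
  }
  dt <- t$dt_M[keep]
  f <- t$intensity[keep]
  out <- data.frame(dt_M = dt, x = dt * f0 / (f0 - f), y = f0 / f)
  attr(out, "excluded") <- excluded
  out
}

#' Estimate the association constant and binding-site number
#'
#' Ordinary least squares of `y = F0/F` on `x = dt*F0/(F0-F)` (see
#' [quench_transform()]): `KA` is the slope and `n = -intercept/(KA * Pt)`.
#' The reported `r` is the Pearson correlation of (x, y), the convention of
#' linearized binding plots.
#'
#' @param t A [fluor_titration()].
#' @return A `binding_fit` list: `ka_per_M`, `n_sites`, `r`,
#'   `temperature_K`, `n_points`, `excluded` (dt of excluded points).
#' @export
estimate_binding <- function(t) {
  xy <- quench_transform(t)
  if (nrow(xy) < 3) {
    ec_stop("insufficient_data", "need >= 3 transformed points")
  }
  fit <- stats::lm(y ~ x, data = xy)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (!is.finite(slope) || slope <= 0) {
    ec_stop("invalid_binding", "slope <= 0: no positive association constant")
  }
  structure(list(ka_per_M = slope,
                 n_sites = -intercept / (slope * t$pt_M),
                 r = stats::cor(xy$x, xy$y),
                 temperature_K = t$temperature_K,
                 n_points = nrow(xy),
                 excluded = attr(xy, "excluded")),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("<binding_fit> %g K: KA = %.4g L/mol, n = %.3g, r = %.4g\n",
              x$temperature_K, x$ka_per_M, x$n_sites, x$r))
  invisible(x)
}

#' Refine a binding fit by nonlinear least squares on the forward model
#'
#' The linearized estimate of [estimate_binding()] is exact on noiseless data
#' but attenuated under intensity noise: the plot abscissa
#' `x = dt*F0/(F0-F)` inherits large relative errors wherever the quench
#' `F0 - F` is a small fraction of `F0`, and ordinary least squares of y on a
#' noisy x biases the slope (KA) low. This refit fits the intensities
#' directly -- `F(dt) = F0*(1 - f(KA, n, Pt, dt))` with `f` the mass-balance
#' bound fraction of [forward_static_quench()] -- by Gauss-Newton least
#' squares, starting from the linear estimate (noise enters only the
#' response, so no attenuation).
#'
#' @param t A [fluor_titration()].
#' @param start Optional `binding_fit` to initialize from; defaults to
#'   `estimate_binding(t)`.
#' @return A `binding_fit` with `ka_per_M`, `n_sites`, `f0` (fitted
#'   baseline), `r` (correlation of fitted vs observed intensity),
#'   `temperature_K`, `method = "nls_forward"`.
#' @export
refine_binding <- function(t, start = NULL) {
  if (!inherits(t, "fluor_titration")) {
    ec_stop("domain_error", "`t` must be a fluor_titration")
  }
  if (is.null(start)) {
    start <- tryCatch(estimate_binding(t), enzchar_error = function(e) NULL)
  }
  ka0 <- if (is.null(start)) 1e5 else max(start$ka_per_M, 1)
  n0 <- if (is.null(start)) 0.5 else min(max(start$n_sites, 0.01), 10)
  df <- data.frame(dt = t$dt_M, obs = t$intensity, pt = t$pt_M)
  fit <- tryCatch(
    suppressWarnings(stats::nls(
      obs ~ f0 * (1 - forward_static_quench(ka, n, pt[1], dt)),
      data = df, start = list(f0 = t$f0, ka = ka0, n = n0),
      algorithm = "port", lower = c(1e-6, 1, 0),
      control = stats::nls.control(maxiter = 200, warnOnly = TRUE))),
    error = function(e) ec_stop("invalid_binding",
                                paste("forward-model refit failed:",
                                      conditionMessage(e))))
  co <- as.list(stats::coef(fit))
  structure(list(ka_per_M = co$ka, n_sites = co$n, f0 = co$f0,
                 r = stats::cor(stats::fitted(fit), t$intensity),
                 temperature_K = t$temperature_K,
                 n_points = length(t$dt_M), method = "nls_forward"),
            class = "binding_fit")
}

#' Classify the quenching mechanism from KA's temperature dependence
#'
#' A ground-state (static) complex dissociates on heating, so KA falls with
#' temperature; collisional (dynamic) quenching intensifies with temperature,
#' so KA rises. Changes within `tol` (relative) are indeterminate.
#'
#' @param fit_low_T,fit_high_T `binding_fit` objects at the lower and higher
#'   temperature (checked).
#' @param tol Relative tolerance, default 0.01.
#' @return One of `"static"`, `"dynamic"`, `"indeterminate"`.
#' @export
classify_quenching <- function(fit_low_T, fit_high_T, tol = 0.01) {
  t1 <- fit_low_T$temperature_K
  t2 <- fit_high_T$temperature_K
  if (!is.finite(t1) || !is.finite(t2) || t1 >= t2) {
    ec_stop("domain_error",
            "fit_low_T must be at a strictly lower temperature than fit_high_T")
  }
  rel <- (fit_low_T$ka_per_M - fit_high_T$ka_per_M) / fit_low_T$ka_per_M
  if (rel > tol) return("static")
  if (rel < -tol) return("dynamic")
  "indeterminate"
}
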