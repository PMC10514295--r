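#' Percent inhibition from control and sample absorbances
#'
#' Computes `100 * (abs_control - abs_sample) / abs_control`, the fractional
#' loss of signal relative to the uninhibited control well. Negative values
#' (apparent activation) are returned as-is with a warning; truncating them
#' to zero would bias the downstream logit line fit.
#'
#' @param abs_control Control absorbance(s), must be > 0.
#' @param abs_sample Sample absorbance(s), must be >= 0.
#' @return Percent inhibition, in (-Inf, 100]. Vectorized.
#' @examples
#' percent_inhibition(1.0, 0.5) # 50
#' @export
percent_inhibition <- function(abs_control, abs_sample) {
  if (!is.numeric(abs_control) || any(!is.finite(abs_control)) ||
      any(abs_control <= 0)) {
    ec_stop("invalid_control", "`abs_control` must be finite and > 0")
  }
  stopifnot_number(abs_sample, "abs_sample", nonnegative = TRUE)
  pct <- 100 * (abs_control - abs_sample) / abs_control
  if (any(pct < 0)) {
    ec_warn("negative_inhibition",
            sprintf("%d value(s) below 0%% inhibition (apparent activation); kept",
                    sum(pct < 0)))
  }
  pct
}

#' Construct a dose-response series
#'
#' @param conc_uM Inhibitor concentrations, uM, all > 0.
#' @param pct_inhibition Percent inhibition at each concentration.
#' @param replicate Integer replicate index per point (default all 1).
#' @param compound_id Text label.
#' @return A `dose_response` object (data frame of points plus label).
#' @export
dose_response <- function(conc_uM, pct_inhibition, replicate = NULL,
                          compound_id = "compound") {
  stopifnot_number(conc_uM, "conc_uM", positive = TRUE)
  stopifnot_number(pct_inhibition, "pct_inhibition")
  if (length(conc_uM) != length(pct_inhibition)) {
    ec_stop("domain_error", "conc_uM and pct_inhibition lengths differ")
  }
  if (is.null(replicate)) replicate <- rep(1L, length(conc_uM))
  if (any(replicate < 1) || any(replicate != as.integer(replicate))) {
    ec_stop("domain_error", "replicate indices must be positive integers")
  }
  if (length(unique(conc_uM)) < 3) {
    ec_stop("insufficient_data",
            "need >= 3 distinct positive concentrations")
  }
  pts <- data.frame(conc_uM = conc_uM, pct_inhibition = pct_inhibition,
                    replicate = as.integer(replicate))
  pts <- pts[order(pts$replicate, pts$conc_uM), , drop = FALSE]
  rownames(pts) <- NULL
  structure(list(compound_id = compound_id, points = pts),
            class = "dose_response")
}

#' @export
print.dose_response <- function(x, ...) {
  cat(sprintf("<dose_response> %s: %d points, %d replicate(s), %g-%g uM\n",
              x$compound_id, nrow(x$points), max(x$points$replicate),
              min(x$points$conc_uM), max(x$points$conc_uM)))
  invisible(x)
}

# Single logit line fit on one set of points. Returns list or NULL when the
# slope is unusable (caller decides whether that is fatal).
logit_fit_one <- function(conc_uM, pct, clip) {
  p <- pmin(pmax(pct / 100, clip[1]), clip[2])
  y <- log(p / (1 - p))
  x <- log10(conc_uM)
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  # suppress summary.lm's perfect-fit warning: noiseless data are routine here
  r2 <- if (stats::var(y) > 0) {
    suppressWarnings(summary(fit)$r.squared)
  } else {
    NA_real_
  }
  list(slope = slope, intercept = intercept, r2 = r2,
       ic50_uM = 10^(-intercept / slope))
}

#' Fit an IC50 by the logit method
#'
#' Linearizes the dose-response as `ln(p/(1-p)) = intercept + slope*log10(c)`
#' with `p = pct/100` clipped to the band `clip`, fits by ordinary least
#' squares, and inverts the 50% point as `IC50 = 10^(-intercept/slope)`.
#' With multiple replicates, each replicate is fit separately and the IC50 is
#' reported as mean +/- sd across replicate fits (the slope, intercept and R2
#' come from the pooled fit over all points).
#'
#' @param dr A [dose_response()] object.
#' @param clip Clip band for p, default `c(0.01, 0.99)`. Points clipped at
#'   both ends are retained but counted in `n_clipped`.
#' @param aggregate If `TRUE`, average percent inhibition per concentration
#'   before fitting (one pooled fit); default `FALSE` fits replicate-level
#'   values.
#' @return An `ic50_fit` list: `ic50_uM`, `sd_uM` (NA for a single
#'   replicate), `slope`, `intercept`, `r2`, `n_points`, `n_clipped`.
#' @export
fit_ic50_logit <- function(dr, clip = c(0.01, 0.99), aggregate = FALSE) {
  if (!inherits(dr, "dose_response")) {
    ec_stop("domain_error", "`dr` must be a dose_response object")
  }
  pts <- dr$points
  if (aggregate) {
    agg <- stats::aggregate(pct_inhibition ~ conc_uM, data = pts, FUN = mean)
    pts <- data.frame(conc_uM = agg$conc_uM, pct_inhibition = agg$pct_inhibition,
                      replicate = 1L)
  }
  if (length(unique(pts$conc_uM)) < 3) {
    ec_stop("insufficient_data", "need >= 3 distinct concentrations")
  }
  pct_band <- 100 * clip
  pct_eff <- pmin(pmax(pts$pct_inhibition, pct_band[1]), pct_band[2])
  if (all(pct_eff < 50) || all(pct_eff > 50)) {
    ec_stop("extrapolation_error",
            "dose-response never crosses 50% inhibition within the clip band")
  }
  n_clipped <- sum(pts$pct_inhibition < pct_band[1] |
                     pts$pct_inhibition > pct_band[2])

  pooled <- logit_fit_one(pts$conc_uM, pts$pct_inhibition, clip)
  if (!is.finite(pooled$slope) || pooled$slope <= 0) {
    ec_stop("non_inhibitor",
            "logit slope <= 0: response does not increase with concentration")
  }

  reps <- sort(unique(pts$replicate))
  if (length(reps) > 1) {
    per_rep <- vapply(reps, function(r) {
      sub <- pts[pts$replicate == r, , drop = FALSE]
      f <- logit_fit_one(sub$conc_uM, sub$pct_inhibition, clip)
      if (!is.finite(f$slope) || f$slope <= 0) NA_real_ else f$ic50_uM
    }, numeric(1))
    if (any(is.na(per_rep))) {
      ec_warn("replicate_dropped",
              sprintf("%d replicate fit(s) had non-positive slope; dropped",
                      sum(is.na(per_rep))))
      per_rep <- per_rep[!is.na(per_rep)]
    }
    if (length(per_rep) == 0) {
      ec_stop("non_inhibitor", "no replicate yielded a positive logit slope")
    }
    ic50 <- mean(per_rep)
    sd_uM <- stats::sd(per_rep)
  } else {
    ic50 <- pooled$ic50_uM
    sd_uM <- NA_real_
  }

  structure(list(compound_id = dr$compound_id, ic50_uM = ic50, sd_uM = sd_uM,
                 slope = pooled$slope, intercept = pooled$intercept,
                 r2 = pooled$r2, n_points = nrow(pts), n_clipped = n_clipped),
            class = "ic50_fit")
}

#' @export
print.ic50_fit <- function(x, ...) {
  cat(sprintf("<ic50_fit> %s: IC50 = %.4g uM%s (slope %.3g, r2 %.4g, n %d)\n",
              x$compound_id, x$ic50_uM,
              if (is.finite(x$sd_uM)) sprintf(" +/- %.3g", x$sd_uM) else "",
              x$slope, x$r2, x$n_points))
  invisible(x)
}

#' Fold potency relative to a reference inhibitor
#'
#' Ratio `ref_ic50_uM / ic50_uM`: how many times more potent the compound is
#' than the reference (values > 1 mean more potent).
#'
#' @param ref_ic50_uM Reference IC50, uM, > 0.
#' @param ic50_uM Compound IC50, uM, > 0.
#' @return Dimensionless ratio.
#' @examples
#' fold_potency(750.0, 12.44) # ~60.3
#' @export
fold_potency <- function(ref_ic50_uM, ic50_uM) {
  stopifnot_number(ref_ic50_uM, "ref_ic50_uM", positive = TRUE)
  stopifnot_number(ic50_uM, "ic50_uM", positive = TRUE)
  ref_ic50_uM / ic50_uM
}

#' Welch t-test of replicate IC50s against a reference compound
#'
#' @param sample_ic50s Numeric vector of replicate IC50s (n >= 2).
#' @param ref_ic50s Numeric vector of reference replicate IC50s (n >= 2).
#' @return List with `t` and `p` (two-sided). Identical constant groups give
#'   t = 0, p = 1 by convention.
#' @export
compare_to_reference <- function(sample_ic50s, ref_ic50s) {
  if (length(sample_ic50s) < 2 || length(ref_ic50s) < 2) {
    ec_stop("insufficient_replicates", "need >= 2 values in each group")
  }
  v1 <- stats::var(sample_ic50s)
  v2 <- stats::var(ref_ic50s)
  if (v1 == 0 && v2 == 0) {
    # t.test() refuses essentially-constant data; define the limits directly
    if (mean(sample_ic50s) == mean(ref_ic50s)) {
      return(list(t = 0, p = 1))
    }
    return(list(t = sign(mean(sample_ic50s) - mean(ref_ic50s)) * Inf, p = 0))
  }
  tt <- stats::t.test(sample_ic50s, ref_ic50s, var.equal = FALSE)
  list(t = unname(tt$statistic), p = tt$p.value)
}
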