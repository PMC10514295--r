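# Independent oracles used to cross-check the package's fitters. These stay
# deliberately naive and share no code with the implementation paths.

# Damped fixed-point solver of the static-quench mass balance
# f = KA (Dt - n Pt f)(1 - f). The damping factor 1/(1 + KA(nPt + Dt))
# bounds the iteration map's derivative below 1, so it contracts.
oracle_bound_fraction <- function(ka, n, pt, dt, tol = 1e-14,
                                  max_iter = 100000L) {
  g <- function(f) ka * (dt - n * pt * f) * (1 - f)
  lam <- 1 / (1 + ka * (n * pt + dt))
  f <- 0
  for (k in seq_len(max_iter)) {
    f_new <- min(max((1 - lam) * f + lam * g(f), 0), 1 - 1e-15)
    if (abs(f_new - f) < tol) return(f_new)
    f <- f_new
  }
  f
}

# Zooming profile search over (KA, n) minimizing squared intensity residuals
# of the forward static-quench model against an observed titration. n is
# profiled out with a 1-D golden search per KA value: joint grid zooming gets
# trapped on the narrow (KA, n) ridge of this SSE surface.
oracle_binding_grid <- function(t, ka_range = c(1e4, 1e6), n_range = c(0, 2),
                                n_grid = 25, n_zoom = 7) {
  f0 <- t$f0
  sse <- function(ka, n) {
    f <- vapply(t$dt_M, function(d) oracle_bound_fraction(ka, n, t$pt_M, d),
                numeric(1))
    sum((t$intensity - f0 * (1 - f))^2)
  }
  profile_n <- function(ka) {
    stats::optimize(function(n) sse(ka, n), interval = n_range,
                    tol = 1e-10)
  }
  for (z in seq_len(n_zoom)) {
    kas <- exp(seq(log(ka_range[1]), log(ka_range[2]), length.out = n_grid))
    prof <- lapply(kas, profile_n)
    errs <- vapply(prof, function(p) p$objective, numeric(1))
    j <- which.min(errs)
    best <- list(ka = kas[j], n = prof[[j]]$minimum)
    span_ka <- (log(ka_range[2]) - log(ka_range[1])) / 4
    ka_range <- exp(log(best$ka) + c(-1, 1) * span_ka)
  }
  list(ka = best$ka, n = best$n)
}

# Direct nonlinear Michaelis-Menten fit (scaleOffset so nls accepts
# zero-residual data).
oracle_mm_fit <- function(s, v) {
  fit <- stats::nls(v ~ vmax * s / (km + s),
                    start = list(vmax = max(v) * 1.2, km = stats::median(s)),
                    control = stats::nls.control(scaleOffset = 1,
                                                 maxiter = 500, tol = 1e-12,
                                                 minFactor = 1e-12))
  as.list(stats::coef(fit))
}
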