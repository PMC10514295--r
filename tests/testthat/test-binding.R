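test_that("quench transform produces the linearized plot coordinates", {
  t <- fluor_titration(293, 4.6e-8, c(0, 1e-6), c(100, 80))
  xy <- quench_transform(t)
  expect_equal(xy$x, 5e-6)
  expect_equal(xy$y, 1.25)
  # constant intensity: nothing to fit
  flat <- suppressWarnings(
    fluor_titration(293, 4.6e-8, c(0, 5e-7, 1e-6), c(100, 100, 100)))
  expect_error(quench_transform(flat), class = "no_quenching")
  expect_error(fluor_titration(293, 4.6e-8, c(1e-7, 1e-6), c(100, 80)),
               class = "missing_baseline")
})

test_that("n = 0 limit collapses to a line through the origin", {
  # closed form F/F0 = 1/(1 + KA dt) makes y = KA x exactly
  t <- gen_titration(4.05e5, 0, temperature_K = 293)
  xy <- quench_transform(t)
  expect_equal(xy$y, 4.05e5 * xy$x, tolerance = 1e-9)
  fit <- estimate_binding(t)
  expect_lt(abs(fit$n_sites), 1e-9)
})

test_that("binding fit recovers the generating constants from noiseless data", {
  t <- gen_titration(4.05e5, 0.3, pt_M = 4.6e-8, temperature_K = 293)
  fit <- estimate_binding(t)
  expect_lt(abs(fit$ka_per_M - 4.05e5) / 4.05e5, 1e-3)
  expect_lt(abs(fit$n_sites - 0.3) / 0.3, 1e-3)
  expect_gt(fit$r, 0.999)
  # property: sweep over plausible KA, n, Pt
  set.seed(13)
  for (k in 1:20) {
    ka <- 10^runif(1, 4, 6)
    n <- runif(1, 0.1, 2)
    pt <- 10^runif(1, -8, -7)
    tt <- gen_titration(ka, n, pt_M = pt, temperature_K = 293)
    f <- estimate_binding(tt)
    expect_lt(abs(f$ka_per_M - ka) / ka, 0.005)
    expect_lt(abs(f$n_sites - n) / n, 0.005)
  }
})

test_that("1% intensity noise keeps median KA error under 10% after refit", {
  # the linearized plot inherits large x-noise where the quench is shallow,
  # attenuating its slope; the forward-model refit removes that bias
  errs <- vapply(1:200, function(s) {
    cfg <- synth_config(seed = s, noise_model = "multiplicative_gaussian",
                        noise_sd_rel = 0.01)
    tt <- gen_titration(4.05e5, 0.3, temperature_K = 293, cfg = cfg)
    fit <- tryCatch(refine_binding(tt), enzchar_error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    abs(fit$ka_per_M - 4.05e5) / 4.05e5
  }, numeric(1))
  expect_lt(median(errs, na.rm = TRUE), 0.10)
})

test_that("forward-model refit agrees with the linear fit on noiseless data", {
  t <- gen_titration(4.05e5, 0.3, pt_M = 4.6e-8, temperature_K = 293)
  lin <- estimate_binding(t)
  ref <- refine_binding(t)
  expect_lt(abs(ref$ka_per_M - lin$ka_per_M) / lin$ka_per_M, 1e-4)
  expect_lt(abs(ref$n_sites - lin$n_sites), 1e-3)
})

test_that("transform-then-fit agrees with a grid-search intensity oracle", {
  # instance chosen so both parameters move the intensities appreciably
  # (n*KA*Pt ~ 0.1); at very low protein the SSE surface is almost flat in n
  # and no finite grid can localize it
  t <- gen_titration(2e5, 1.0, pt_M = 5e-7, temperature_K = 293)
  fit <- estimate_binding(t)
  oracle <- oracle_binding_grid(t, ka_range = c(1e4, 1e6), n_range = c(0, 2))
  expect_lt(abs(fit$ka_per_M - oracle$ka) / oracle$ka, 0.01)
  expect_lt(abs(fit$n_sites - oracle$n), 0.01 * max(oracle$n, 1))
})

test_that("bound fraction is nondecreasing in ligand concentration", {
  dt <- seq(0, 1e-6, length.out = 21)
  f <- forward_static_quench(4.05e5, 0.3, 4.6e-8, dt)
  expect_true(all(diff(f) >= 0))
  expect_true(all(f >= 0 & f < 1))
})

test_that("quenching mechanism follows KA's temperature dependence", {
  mk <- function(ka, t_K) {
    structure(list(ka_per_M = ka, n_sites = 0.3, r = 0.99,
                   temperature_K = t_K), class = "binding_fit")
  }
  expect_identical(classify_quenching(mk(40.5e4, 293), mk(36.6e4, 333)),
                   "static")
  expect_identical(classify_quenching(mk(1e4, 293), mk(2e4, 333)), "dynamic")
  expect_identical(classify_quenching(mk(1e5, 293), mk(1e5, 333)),
                   "indeterminate")
  expect_error(classify_quenching(mk(1e5, 333), mk(1e5, 293)),
               class = "domain_error")
})
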