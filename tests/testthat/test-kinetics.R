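test_that("Michaelis-Menten velocity matches its defining ratios", {
  expect_equal(michaelis_menten_velocity(1, 2, 2), 0.5)
  expect_lt(abs(michaelis_menten_velocity(1, 2, 2e6) - 1), 1e-6)
  # at [I] = Ki, Km doubles: s = Km_app gives half-maximal rate
  expect_equal(michaelis_menten_velocity(1, km_app(2, 5, 5), 4), 0.5)
  expect_error(michaelis_menten_velocity(-1, 2, 2), class = "domain_error")
})

test_that("apparent Km scales linearly with inhibitor concentration", {
  expect_equal(km_app(1.7, 0, 11), 1.7)
  expect_equal(km_app(1.7, 11, 11), 3.4)
  expect_equal(round(km_app(1.0, 12.4, 11.0), 3), 2.127)
  # strictly increasing in [I], strictly decreasing in Ki
  i <- seq(0, 20, by = 2.5)
  expect_true(all(diff(km_app(1, i, 11)) > 0))
  kis <- c(1, 5, 20, 100)
  expect_true(all(diff(vapply(kis, function(k) km_app(1, 10, k),
                              numeric(1))) < 0))
  expect_error(km_app(1, 5, 0), class = "domain_error")
})

test_that("double-reciprocal fit recovers the exact generating line", {
  s <- c(1, 2, 4, 8)
  v <- s / (2 + s)
  fit <- lineweaver_burk_fit(s, v)
  expect_equal(fit$slope, 2.0, tolerance = 1e-9)
  expect_equal(fit$intercept, 1.0, tolerance = 1e-9)
  expect_equal(fit$km_app_mM, 2.0, tolerance = 1e-9)
  expect_equal(fit$vmax, 1.0, tolerance = 1e-9)
  expect_warning(deg <- lineweaver_burk_fit(s, rep(0.9, 4)),
                 class = "degenerate_data")
  expect_equal(deg$slope, 0)
  expect_equal(deg$km_app_mM, 0)
  expect_error(lineweaver_burk_fit(c(1, 2), c(0.3, 0.5)),
               class = "insufficient_data")
})

test_that("double-reciprocal Km_app agrees with a direct nonlinear fit", {
  set.seed(8)
  for (k in 1:10) {
    km <- runif(1, 0.5, 10); vmax <- runif(1, 0.5, 5)
    s <- seq_len(10)
    v <- vmax * s / (km + s)
    lb <- lineweaver_burk_fit(s, v)
    nl <- oracle_mm_fit(s, v)
    expect_lt(abs(lb$km_app_mM - nl$km) / nl$km, 1e-8)
    expect_lt(abs(lb$vmax - nl$vmax) / nl$vmax, 1e-8)
  }
})

test_that("secondary replot extracts Ki as intercept over slope", {
  i <- c(0, 3.1, 6.2, 12.4)
  res <- ki_from_replot(i, km_app(1, i, 11.0))
  expect_lt(abs(res$ki_uM - 11.0) / 11.0, 1e-9)
  expect_lt(abs(res$km_mM - 1.0), 1e-9)
  two <- ki_from_replot(c(0, 2), c(2, 4))
  expect_equal(two$ki_uM, 2.0)
  expect_equal(two$km_mM, 2.0)
  expect_error(ki_from_replot(c(0, 5, 10), c(3, 2, 1)),
               class = "no_inhibition")
})

test_that("noiseless competitive data round-trip through the full pipeline", {
  set.seed(21)
  for (k in 1:15) {
    km <- runif(1, 0.5, 10)
    ki <- 10^runif(1, 0, 2)
    vmax <- runif(1, 0.5, 5)
    vds <- gen_velocity_dataset(km, vmax, ki)
    res <- analyze_kinetics(vds)
    expect_lt(abs(res$ki_uM - ki) / ki, 1e-6)
    expect_lt(abs(res$km_mM - km) / km, 1e-6)
    expect_identical(res$mode, "competitive")
  }
})

test_that("inhibition mode classification matches the canonical patterns", {
  mk <- function(i, km, vm) {
    structure(list(inhibitor_uM = i, km_app_mM = km, vmax = vm),
              class = "kinetic_fit")
  }
  i <- c(0, 3.1, 6.2, 12.4)
  competitive <- Map(mk, i, c(1, 1.28, 1.56, 2.13), rep(1, 4))
  expect_identical(classify_inhibition_mode(competitive), "competitive")
  noncomp <- Map(mk, c(0, 5, 10), rep(2, 3), c(1, 0.8, 0.6))
  expect_identical(classify_inhibition_mode(noncomp), "noncompetitive")
  uncomp <- Map(mk, c(0, 5, 10), c(2, 1.5, 1), c(1, 0.75, 0.5))
  expect_identical(classify_inhibition_mode(uncomp), "uncompetitive")
  mixed <- Map(mk, c(0, 5, 10), c(1, 1.5, 2), c(1, 0.8, 0.6))
  expect_identical(classify_inhibition_mode(mixed), "mixed")
  expect_error(classify_inhibition_mode(competitive[1]),
               class = "insufficient_data")
})

test_that("competitive generation classifies competitive under 2% noise", {
  hits <- vapply(1:100, function(s) {
    cfg <- synth_config(seed = s, noise_model = "multiplicative_gaussian",
                        noise_sd_rel = 0.02)
    vds <- gen_velocity_dataset(1, 1, 11, cfg = cfg)
    analyze_kinetics(vds)$mode == "competitive"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
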