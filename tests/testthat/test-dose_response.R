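test_that("percent inhibition follows the control-normalized difference", {
  expect_equal(percent_inhibition(1.0, 0.5), 50.0)
  expect_equal(percent_inhibition(0.73, 0.73), 0.0)
  expect_equal(percent_inhibition(0.8, 0.0), 100.0)
  expect_warning(val <- percent_inhibition(0.5, 0.6),
                 class = "negative_inhibition")
  expect_lt(val, 0)
  expect_error(percent_inhibition(0, 0.5), class = "invalid_control")
  expect_error(percent_inhibition(-1, 0.5), class = "invalid_control")
})

test_that("percent inhibition is invariant to joint rescaling of absorbances", {
  set.seed(11)
  for (k in 1:25) {
    ctrl <- runif(1, 0.2, 2)
    samp <- runif(1, 0, ctrl)
    scale <- runif(1, 0.1, 10)
    expect_equal(percent_inhibition(ctrl * scale, samp * scale),
                 percent_inhibition(ctrl, samp))
  }
})

test_that("logit fit inverts noiseless one-site curves exactly", {
  # fixed worked examples first
  dr <- gen_dose_response(100, 1, c(25, 50, 100, 200, 400))
  expect_lt(abs(fit_ic50_logit(dr)$ic50_uM - 100) / 100, 1e-9)
  dr2 <- gen_dose_response(12.44, 1, c(3.11, 6.22, 12.44, 24.88, 49.76))
  expect_lt(abs(fit_ic50_logit(dr2)$ic50_uM - 12.44) / 12.44, 1e-9)
  # property: any IC50 in [1, 1000] uM, any >=3-point geometric grid around it
  set.seed(42)
  for (k in 1:40) {
    ic50 <- 10^runif(1, 0, 3)
    n_pts <- sample(3:8, 1)
    ratio <- runif(1, 1.5, 4)
    grid <- ic50 * ratio^(seq(-(n_pts - 1) / 2, (n_pts - 1) / 2))
    fit <- fit_ic50_logit(gen_dose_response(ic50, 1, grid))
    expect_lt(abs(fit$ic50_uM - ic50) / ic50, 1e-6)
    expect_gt(fit$slope, 0)
  }
})

test_that("logit fit rejects degenerate dose-response inputs", {
  expect_error(dose_response(c(10, 20), c(20, 40)),
               class = "insufficient_data")
  # never crosses 50% within the clip band
  low <- dose_response(c(1, 2, 4), c(1, 2, 4))
  expect_error(fit_ic50_logit(low), class = "extrapolation_error")
  # response falling with concentration: not an inhibitor
  falling <- dose_response(c(1, 10, 100), c(80, 50, 20))
  expect_error(fit_ic50_logit(falling), class = "non_inhibitor")
})

test_that("replicated fits report mean and sd across per-replicate IC50s", {
  cfg <- synth_config(seed = 7, noise_model = "multiplicative_gaussian",
                      noise_sd_rel = 0.05)
  dr <- gen_dose_response(50, 1, c(12.5, 25, 50, 100, 200), cfg,
                          n_replicates = 3L)
  fit <- fit_ic50_logit(dr)
  expect_true(is.finite(fit$sd_uM) && fit$sd_uM >= 0)
  expect_lt(abs(fit$ic50_uM - 50) / 50, 0.25)
  # aggregate = TRUE collapses replicates into one pooled fit
  fit_agg <- fit_ic50_logit(dr, aggregate = TRUE)
  expect_true(is.na(fit_agg$sd_uM))
})

test_that("5% noise still recovers IC50 within 10% median relative error", {
  ic50 <- 50
  grid <- c(12.5, 25, 50, 100, 200)
  errs <- vapply(1:100, function(s) {
    cfg <- synth_config(seed = s, noise_model = "multiplicative_gaussian",
                        noise_sd_rel = 0.05)
    fit <- fit_ic50_logit(gen_dose_response(ic50, 1, grid, cfg))
    abs(fit$ic50_uM - ic50) / ic50
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})

test_that("fold potency is the reference ratio and multiplicative inverse", {
  expect_equal(round(fold_potency(750.0, 12.44), 1), 60.3)
  expect_equal(fold_potency(5, 5), 1.0)
  expect_equal(fold_potency(750.0, 375.0), 2.0)
  set.seed(3)
  for (k in 1:20) {
    a <- runif(1, 1, 1000); b <- runif(1, 1, 1000)
    expect_equal(fold_potency(a, b) * fold_potency(b, a), 1.0)
  }
  expect_error(fold_potency(-1, 5), class = "domain_error")
})

test_that("Welch comparison against the reference behaves at the edges", {
  same <- compare_to_reference(c(3, 3, 3), c(3, 3, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  set.seed(5)
  sample_ic50 <- rnorm(3, 12.44, 0.38)
  ref_ic50 <- rnorm(3, 750.0, 1.5)
  res <- compare_to_reference(sample_ic50, ref_ic50)
  expect_lt(res$p, 0.001)
  expect_error(compare_to_reference(5, c(1, 2)),
               class = "insufficient_replicates")
})
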