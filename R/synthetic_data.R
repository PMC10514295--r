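#' Configuration for synthetic dataset generation
#'
#' @param seed Integer seed; every generator scopes its RNG use to this seed
#'   (no global random state is touched).
#' @param noise_model `"none"` or `"multiplicative_gaussian"` (signal scaled
#'   by `1 + N(0, noise_sd_rel)`; plate-reader error is close to constant-CV).
#' @param noise_sd_rel Relative noise sd, >= 0; must be 0 iff
#'   `noise_model = "none"`.
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1L,
                         noise_model = c("none", "multiplicative_gaussian"),
                         noise_sd_rel = 0) {
  noise_model <- match.arg(noise_model)
  stopifnot_number(noise_sd_rel, "noise_sd_rel", nonnegative = TRUE)
  if ((noise_sd_rel == 0) != (noise_model == "none")) {
    ec_stop("domain_error",
            "noise_sd_rel must be 0 exactly when noise_model is 'none'")
  }
  structure(list(seed = as.integer(seed), noise_model = noise_model,
                 noise_sd_rel = noise_sd_rel),
            class = "synth_config")
}

# multiplicative gaussian noise, clipped at a positivity floor; assumes the
# caller has already scoped the RNG with the config seed
apply_noise <- function(x, cfg) {
  if (cfg$noise_model == "none") return(x)
  pmax(x * (1 + stats::rnorm(length(x), 0, cfg$noise_sd_rel)), 1e-12)
}

#' Generate a synthetic logistic dose-response series
#'
#' Forward one-site model `pct(c) = 100 / (1 + (ic50/c)^hill_slope)`, noised
#' per `cfg`. Deterministic for a fixed seed and configuration.
#'
#' @param ic50_uM Generating IC50, uM, > 0.
#' @param hill_slope Hill slope, > 0 (1 for the plain one-site curve the
#'   logit fit inverts exactly).
#' @param conc_grid_uM Concentrations, uM, all > 0.
#' @param cfg A [synth_config()].
#' @param n_replicates Replicates per concentration, default 1.
#' @param compound_id Label for the series.
#' @return A [dose_response()] object.
#' @export
gen_dose_response <- function(ic50_uM, hill_slope, conc_grid_uM,
                              cfg = synth_config(), n_replicates = 1L,
                              compound_id = "synthetic") {
  stopifnot_number(ic50_uM, "ic50_uM", positive = TRUE)
  stopifnot_number(hill_slope, "hill_slope", positive = TRUE)
  if (length(conc_grid_uM) == 0) {
    ec_stop("domain_error", "conc_grid_uM must be non-empty")
  }
  stopifnot_number(conc_grid_uM, "conc_grid_uM", positive = TRUE)
  conc <- rep(sort(conc_grid_uM), times = n_replicates)
  rep_idx <- rep(seq_len(n_replicates), each = length(conc_grid_uM))
  pct <- 100 / (1 + (ic50_uM / conc)^hill_slope)
  pct <- withr::with_seed(cfg$seed, apply_noise(pct, cfg))
  dose_response(conc, pct, replicate = rep_idx, compound_id = compound_id)
}

#' Generate a synthetic competitive-inhibition velocity dataset
#'
#' Forward model `v(i, s) = vmax * s / (km*(1 + i/ki) + s)` over the
#' substrate x inhibitor grid, noised per `cfg`.
#'
#' @param km_mM Uninhibited Michaelis constant, mM, > 0.
#' @param vmax Maximum velocity, > 0.
#' @param ki_uM Inhibition constant, uM, > 0.
#' @param s_grid_mM Substrate grid, mM (default 1-10 mM).
#' @param i_grid_uM Inhibitor grid, uM, must include 0 (default
#'   0, 3.1, 6.2, 12.4 uM).
#' @param cfg A [synth_config()].
#' @return A [velocity_dataset()].
#' @export
gen_velocity_dataset <- function(km_mM, vmax, ki_uM,
                                 s_grid_mM = 1:10,
                                 i_grid_uM = c(0, 3.1, 6.2, 12.4),
                                 cfg = synth_config()) {
  stopifnot_number(km_mM, "km_mM", positive = TRUE)
  stopifnot_number(vmax, "vmax", positive = TRUE)
  stopifnot_number(ki_uM, "ki_uM", positive = TRUE)
  if (length(s_grid_mM) == 0 || length(i_grid_uM) == 0) {
    ec_stop("domain_error", "grids must be non-empty")
  }
  s <- sort(s_grid_mM)
  i <- sort(i_grid_uM)
  v <- outer(km_app(km_mM, i, ki_uM), s,
             function(ka, ss) vmax * ss / (ka + ss))
  v <- withr::with_seed(cfg$seed, apply_noise(v, cfg))
  velocity_dataset(i, s, matrix(v, nrow = length(i)))
}

#' Bound protein fraction under the static-quench mass balance
#'
#' Solves the ground-state complexation equilibrium
#' `KA = [DnP] / ([Df][Pf])` with mass balances `Pt = Pf + DnP` and
#' `Df = Dt - n*DnP` for the bound fraction `f = [DnP]/Pt`, which satisfies
#' `KA*n*Pt*f^2 - (1 + KA*n*Pt + KA*dt)*f + KA*dt = 0`. The smaller root is
#' returned: the polynomial is positive at f = 0 (value `KA*dt`) and negative
#' at f = 1 (value -1), so exactly one root lies in \[0, 1) and it is the
#' smaller of the two. The fluorescence ratio follows as `F/F0 = 1 - f`.
#'
#' @param ka_per_M Association constant, L/mol, >= 0.
#' @param n_sites Binding-site number, >= 0.
#' @param pt_M Total protein, mol/L, > 0.
#' @param dt_M Total ligand, mol/L, >= 0. Vectorized.
#' @return Bound fraction(s) in \[0, 1).
#' @export
forward_static_quench <- function(ka_per_M, n_sites, pt_M, dt_M) {
  stopifnot_number(ka_per_M, "ka_per_M", nonnegative = TRUE)
  stopifnot_number(n_sites, "n_sites", nonnegative = TRUE)
  stopifnot_number(pt_M, "pt_M", positive = TRUE)
  stopifnot_number(dt_M, "dt_M", nonnegative = TRUE)
  a <- ka_per_M * n_sites * pt_M
  b <- 1 + a + ka_per_M * dt_M
  cc <- ka_per_M * dt_M
  if (a == 0) {
    # linear limit (n = 0 or KA = 0): f = KA*dt / (1 + KA*dt)
    f <- cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (any(disc < 0)) {
      ec_stop("model_violation", "negative discriminant in mass balance")
    }
    # smaller root via the numerically stable form 2c / (b + sqrt(disc))
    f <- 2 * cc / (b + sqrt(disc))
  }
  if (any(f < 0 | f >= 1)) {
    ec_stop("model_violation", "no bound-fraction root in [0, 1)")
  }
  f
}

#' Generate a synthetic static-quench fluorescence titration
#'
#' `F(dt) = f0_intensity * (1 - forward_static_quench(...))`, noised per
#' `cfg`.
#'
#' @param ka_per_M Association constant, L/mol.
#' @param n_sites Binding-site number.
#' @param pt_M Total protein, mol/L (assay default 4.6e-8).
#' @param dt_grid_M Ligand grid, mol/L, must include 0.
#' @param f0_intensity Unquenched intensity, > 0.
#' @param temperature_K Temperature, K.
#' @param cfg A [synth_config()].
#' @return A [fluor_titration()].
#' @export
gen_titration <- function(ka_per_M, n_sites, pt_M = 4.6e-8,
                          dt_grid_M = c(0, seq(1e-7, 1e-6, by = 1e-7)),
                          f0_intensity = 1000, temperature_K = 293,
                          cfg = synth_config()) {
  if (!any(dt_grid_M == 0)) {
    ec_stop("missing_baseline", "dt_grid_M must include 0 (defines F0)")
  }
  stopifnot_number(f0_intensity, "f0_intensity", positive = TRUE)
  dt <- sort(dt_grid_M)
  f <- forward_static_quench(ka_per_M, n_sites, pt_M, dt)
  intensity <- f0_intensity * (1 - f)
  intensity <- withr::with_seed(cfg$seed, apply_noise(intensity, cfg))
  suppressWarnings(
    fluor_titration(temperature_K, pt_M, dt, intensity)
  )
}
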