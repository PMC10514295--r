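#' @keywords internal
R_GAS <- 8.314 # J/(mol K)

#' Van't Hoff enthalpy from two association constants
#'
#' Standard two-point van't Hoff relation
#' `ln(K2/K1) = -(dH/R) * (1/T2 - 1/T1)`, solved for dH. A binding constant
#' that falls on heating therefore yields a negative (exothermic) enthalpy.
#'
#' @param ka1_per_M Association constant at `t1_K`, L/mol.
#' @param t1_K First absolute temperature, K.
#' @param ka2_per_M Association constant at `t2_K`, L/mol.
#' @param t2_K Second absolute temperature, K (different from `t1_K`).
#' @return Enthalpy change, kJ/mol.
#' @export
vant_hoff_enthalpy <- function(ka1_per_M, t1_K, ka2_per_M, t2_K) {
  stopifnot_number(ka1_per_M, "ka1_per_M", positive = TRUE)
  stopifnot_number(ka2_per_M, "ka2_per_M", positive = TRUE)
  stopifnot_number(t1_K, "t1_K", positive = TRUE)
  stopifnot_number(t2_K, "t2_K", positive = TRUE)
  if (t1_K == t2_K) {
    ec_stop("domain_error", "t1_K and t2_K must differ")
  }
  -R_GAS * log(ka2_per_M / ka1_per_M) / (1 / t2_K - 1 / t1_K) / 1000
}

#' Gibbs free energy from an association constant
#'
#' `dG = -R * T * ln(KA)`, in kJ/mol.
#'
#' @param ka_per_M Association constant, L/mol, > 0.
#' @param t_K Absolute temperature, K, > 0.
#' @return Free-energy change, kJ/mol.
#' @export
gibbs_from_ka <- function(ka_per_M, t_K) {
  stopifnot_number(ka_per_M, "ka_per_M", positive = TRUE)
  stopifnot_number(t_K, "t_K", positive = TRUE)
  -R_GAS * t_K * log(ka_per_M) / 1000
}

#' Gibbs free energy from enthalpy and entropy
#'
#' `dG = dH - T * dS` (dS in J/(mol K), result in kJ/mol).
#'
#' @param dh_kJ_mol Enthalpy change, kJ/mol.
#' @param ds_J_mol_K Entropy change, J/(mol K).
#' @param t_K Absolute temperature, K, > 0.
#' @return Free-energy change, kJ/mol.
#' @export
gibbs_from_enthalpy_entropy <- function(dh_kJ_mol, ds_J_mol_K, t_K) {
  stopifnot_number(dh_kJ_mol, "dh_kJ_mol")
  stopifnot_number(ds_J_mol_K, "ds_J_mol_K")
  stopifnot_number(t_K, "t_K", positive = TRUE)
  dh_kJ_mol - t_K * ds_J_mol_K / 1000
}

#' Entropy change from enthalpy and free energy
#'
#' Rearranged `dG = dH - T*dS`: `dS = 1000*(dH - dG)/T`, in J/(mol K).
#'
#' @param dh_kJ_mol Enthalpy change, kJ/mol.
#' @param dg_kJ_mol Free-energy change, kJ/mol.
#' @param t_K Absolute temperature, K, > 0.
#' @return Entropy change, J/(mol K).
#' @export
entropy_from <- function(dh_kJ_mol, dg_kJ_mol, t_K) {
  stopifnot_number(dh_kJ_mol, "dh_kJ_mol")
  stopifnot_number(dg_kJ_mol, "dg_kJ_mol")
  stopifnot_number(t_K, "t_K", positive = TRUE)
  1000 * (dh_kJ_mol - dg_kJ_mol) / t_K
}

#' Classify the dominant non-covalent interaction from thermodynamic signs
#'
#' Sign-rule classification for protein-ligand binding: dH > 0 with dS > 0
#' indicates hydrophobic interactions; dH < 0 with dS < 0 indicates hydrogen
#' bonding and van der Waals contacts; dH < 0 with dS > 0 indicates
#' electrostatic forces. Any other combination (including exact zeros) is
#' unclassified.
#'
#' @param dh_kJ_mol Enthalpy change, kJ/mol.
#' @param ds_J_mol_K Entropy change, J/(mol K).
#' @return One of `"hydrophobic"`, `"hbond_vdw"`, `"electrostatic"`,
#'   `"unclassified"`.
#' @export
classify_forces <- function(dh_kJ_mol, ds_J_mol_K) {
  stopifnot_number(dh_kJ_mol, "dh_kJ_mol")
  stopifnot_number(ds_J_mol_K, "ds_J_mol_K")
  if (dh_kJ_mol > 0 && ds_J_mol_K > 0) return("hydrophobic")
  if (dh_kJ_mol < 0 && ds_J_mol_K < 0) return("hbond_vdw")
  if (dh_kJ_mol < 0 && ds_J_mol_K > 0) return("electrostatic")
  "unclassified"
}

#' Assemble a two-temperature thermodynamic profile
#'
#' Computes dH by the two-point van't Hoff relation, dG at the reference
#' temperature (default the lower measurement temperature) from
#' `-RT ln KA`, dS from the Gibbs identity, and classifies the dominant
#' interaction force. Both dG routes are reported: `dg_from_ka_kJ_mol`
#' (direct from the binding constant) is the one used to derive dS; the
#' Gibbs identity `dG = dH - T dS` then holds exactly by construction.
#'
#' @param ka1_per_M,t1_K Association constant (L/mol) and temperature (K) of
#'   the first (lower-T) measurement.
#' @param ka2_per_M,t2_K Second measurement.
#' @param t_ref_K Reference temperature for dG/dS; defaults to
#'   `min(t1_K, t2_K)`.
#' @return A `thermo_profile` list: `dh_kJ_mol`, `dg_kJ_mol`, `ds_J_mol_K`,
#'   `t_ref_K`, `force_class`, and provenance of each route.
#' @export
thermodynamic_profile <- function(ka1_per_M, t1_K, ka2_per_M, t2_K,
                                  t_ref_K = min(t1_K, t2_K)) {
  dh <- vant_hoff_enthalpy(ka1_per_M, t1_K, ka2_per_M, t2_K)
  ka_ref <- if (t_ref_K == t1_K) ka1_per_M else ka2_per_M
  dg <- gibbs_from_ka(ka_ref, t_ref_K)
  ds <- entropy_from(dh, dg, t_ref_K)
  structure(list(dh_kJ_mol = dh, dg_kJ_mol = dg, ds_J_mol_K = ds,
                 t_ref_K = t_ref_K,
                 force_class = classify_forces(dh, ds),
                 provenance = list(
                   dh = "two-point van't Hoff on (ka1, t1), (ka2, t2)",
                   dg = "-RT ln KA at t_ref",
                   ds = "(dH - dG)/T at t_ref")),
            class = "thermo_profile")
}

#' @export
print.thermo_profile <- function(x, ...) {
  cat(sprintf(paste0("<thermo_profile> dH = %.3g kJ/mol, dG = %.3g kJ/mol, ",
                     "dS = %.3g J/(mol K) at %g K -> %s\n"),
              x$dh_kJ_mol, x$dg_kJ_mol, x$ds_J_mol_K, x$t_ref_K,
              x$force_class))
  invisible(x)
}
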