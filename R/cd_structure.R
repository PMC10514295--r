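#' Secondary-structure composition from CD deconvolution
#'
#' Three-class composition (alpha-helix, beta-turn, random coil) as reported
#' by CD spectral deconvolution software. The three percentages must sum to
#' 100 within `tau_sum` (absorbs deconvolution rounding).
#'
#' @param label Text label (e.g. "control", a compound id).
#' @param helix_pct,turn_pct,coil_pct Percentages in \[0, 100\].
#' @param tau_sum Allowed deviation of the sum from 100, default 2.0.
#' @return A `ss_composition` list.
#' @export
ss_composition <- function(label, helix_pct, turn_pct, coil_pct,
                           tau_sum = 2.0) {
  for (v in list(helix_pct, turn_pct, coil_pct)) {
    stopifnot_number(v, "composition percentage", nonnegative = TRUE)
    if (v > 100) ec_stop("invalid_composition", "percentage above 100")
  }
  total <- helix_pct + turn_pct + coil_pct
  if (abs(total - 100) > tau_sum) {
    ec_stop("invalid_composition",
            sprintf("composition sums to %.1f%%, outside 100 +/- %.1f", total,
                    tau_sum))
  }
  structure(list(label = label, helix_pct = helix_pct, turn_pct = turn_pct,
                 coil_pct = coil_pct),
            class = "ss_composition")
}

#' Compare secondary-structure compositions (treated - control)
#'
#' @param control,treated [ss_composition()] objects.
#' @return List with `delta_helix_pct`, `delta_turn_pct`, `delta_coil_pct`
#'   (treated minus control, percentage points) and a `summary` string naming
#'   the direction of each change.
#' @export
compare_composition <- function(control, treated) {
  if (!inherits(control, "ss_composition") ||
      !inherits(treated, "ss_composition")) {
    ec_stop("domain_error", "inputs must be ss_composition objects")
  }
  d <- c(helix = treated$helix_pct - control$helix_pct,
         turn = treated$turn_pct - control$turn_pct,
         coil = treated$coil_pct - control$coil_pct)
  word <- function(x) {
    if (x > 0) "increased" else if (x < 0) "decreased" else "unchanged"
  }
  summary <- sprintf(
    "alpha-helix %s (%+.1f), beta-turn %s (%+.1f), random coil %s (%+.1f)",
    word(d["helix"]), d["helix"], word(d["turn"]), d["turn"],
    word(d["coil"]), d["coil"])
  list(delta_helix_pct = unname(d["helix"]),
       delta_turn_pct = unname(d["turn"]),
       delta_coil_pct = unname(d["coil"]),
       summary = summary)
}
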