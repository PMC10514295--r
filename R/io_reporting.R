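# CSV schemas: comma-separated, UTF-8, '.' decimal, mandatory header.
# Temperatures are accepted in Celsius in files and converted with +273
# (the assay convention maps 20 C -> 293 K).

celsius_to_kelvin <- function(t_C) t_C + 273

ec_schemas <- list(
  assay = list(cols = c("compound_id", "conc_um", "replicate",
                        "abs_control", "abs_sample"),
               numeric = c("conc_um", "abs_control", "abs_sample"),
               integer = "replicate"),
  velocity = list(cols = c("inhibitor_um", "substrate_mm", "velocity"),
                  numeric = c("inhibitor_um", "substrate_mm", "velocity"),
                  integer = character(0)),
  titration = list(cols = c("temperature_c", "dt_um", "fluorescence"),
                   numeric = c("temperature_c", "dt_um", "fluorescence"),
                   integer = character(0),
                   optional = "background"),
  composition = list(cols = c("label", "helix_pct", "turn_pct", "coil_pct"),
                     numeric = c("helix_pct", "turn_pct", "coil_pct"),
                     integer = character(0))
)

#' Read and validate a typed CSV table
#'
#' Reads one of the pipeline's CSV schemas (`"assay"`, `"velocity"`,
#' `"titration"`, `"composition"`), matching the header case-insensitively,
#' coercing columns to their declared types, and reporting unparseable cells
#' with their line number.
#'
#' @param path CSV file path.
#' @param schema_name One of the schema names above.
#' @return Data frame with canonical lower-case column names.
#' @export
read_table <- function(path, schema_name = names(ec_schemas)) {
  schema_name <- match.arg(schema_name)
  schema <- ec_schemas[[schema_name]]
  if (!file.exists(path)) {
    ec_stop("file_not_found", sprintf("no such file: %s", path))
  }
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  if (nrow(raw) == 0) {
    ec_stop("empty_input", sprintf("%s has a header but no rows", path))
  }
  names(raw) <- tolower(trimws(names(raw)))
  missing <- setdiff(schema$cols, names(raw))
  if (length(missing) > 0) {
    ec_stop("schema_error",
            sprintf("%s: missing column(s): %s", path,
                    paste(missing, collapse = ", ")))
  }
  keep <- intersect(c(schema$cols, schema$optional), names(raw))
  out <- raw[, keep, drop = FALSE]
  for (col in intersect(c(schema$numeric, schema$integer,
                          schema$optional), keep)) {
    parsed <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(is.na(parsed) & !(trimws(out[[col]]) %in% c("", "NA")))
    if (length(bad) > 0) {
      # +1 for the header line
      ec_stop("parse_error",
              sprintf("%s: column '%s', line %d: cannot parse '%s' as number",
                      path, col, bad[1] + 1L, out[[col]][bad[1]]))
    }
    out[[col]] <- if (col %in% schema$integer) as.integer(parsed) else parsed
  }
  out
}

#' Read an inhibition assay CSV into per-compound dose-response objects
#'
#' Expects columns `compound_id, conc_uM, replicate, abs_control, abs_sample`.
#' Percent inhibition is computed per row; rows with `conc_uM = 0` are
#' dropped (they carry no dose information for the logit fit).
#'
#' @param path CSV file path.
#' @return Named list of [dose_response()] objects, one per compound.
#' @export
read_assay_csv <- function(path) {
  tab <- read_table(path, "assay")
  tab$pct <- percent_inhibition(tab$abs_control, tab$abs_sample)
  tab <- tab[tab$conc_um > 0, , drop = FALSE]
  out <- lapply(split(tab, tab$compound_id), function(sub) {
    dose_response(sub$conc_um, sub$pct, replicate = sub$replicate,
                  compound_id = sub$compound_id[1])
  })
  out[order(names(out))]
}

#' Read a long-format velocity CSV into a velocity dataset
#'
#' Expects columns `inhibitor_uM, substrate_mM, velocity`, one row per grid
#' cell (the full inhibitor x substrate cross must be present).
#'
#' @param path CSV file path.
#' @return A [velocity_dataset()].
#' @export
read_velocity_csv <- function(path) {
  tab <- read_table(path, "velocity")
  i <- sort(unique(tab$inhibitor_um))
  s <- sort(unique(tab$substrate_mm))
  v <- matrix(NA_real_, nrow = length(i), ncol = length(s))
  for (r in seq_len(nrow(tab))) {
    v[match(tab$inhibitor_um[r], i), match(tab$substrate_mm[r], s)] <-
      tab$velocity[r]
  }
  if (any(is.na(v))) {
    ec_stop("schema_error", "velocity table is not a full inhibitor x substrate grid")
  }
  velocity_dataset(i, s, v)
}

#' Read a fluorescence titration CSV (one temperature per series)
#'
#' Expects columns `temperature_C, dt_uM, fluorescence` and optionally
#' `background` (subtracted per point when present). Concentrations are
#' converted to mol/L and temperatures to K internally. One
#' [fluor_titration()] is returned per distinct temperature.
#'
#' @param path CSV file path.
#' @param pt_nM Total protein concentration, nM (assay default 46).
#' @return Named list of [fluor_titration()] objects keyed by temperature (K).
#' @export
read_titration_csv <- function(path, pt_nM = 46) {
  tab <- read_table(path, "titration")
  if (!is.null(tab$background)) {
    tab$fluorescence <- tab$fluorescence - tab$background
  }
  out <- lapply(split(tab, tab$temperature_c), function(sub) {
    sub <- sub[order(sub$dt_um), , drop = FALSE]
    fluor_titration(celsius_to_kelvin(sub$temperature_c[1]),
                    pt_nM * 1e-9, sub$dt_um * 1e-6, sub$fluorescence)
  })
  names(out) <- vapply(out, function(t) as.character(t$temperature_K),
                       character(1))
  out[order(as.numeric(names(out)))]
}

#' Read a secondary-structure composition CSV
#'
#' Expects columns `label, helix_pct, turn_pct, coil_pct`.
#'
#' @param path CSV file path.
#' @param tau_sum Sum tolerance passed to [ss_composition()].
#' @return Named list of [ss_composition()] objects keyed by label.
#' @export
read_composition_csv <- function(path, tau_sum = 2.0) {
  tab <- read_table(path, "composition")
  out <- lapply(seq_len(nrow(tab)), function(r) {
    ss_composition(tab$label[r], tab$helix_pct[r], tab$turn_pct[r],
                   tab$coil_pct[r], tau_sum = tau_sum)
  })
  names(out) <- tab$label
  out
}

# round every numeric leaf to 6 significant digits so serialization is
# deterministic and readable
round_sig <- function(x) {
  if (is.list(x)) return(lapply(x, round_sig))
  if (is.numeric(x)) return(signif(x, 6))
  x
}

#' Build a single-compound characterization report
#'
#' Aggregates the per-stage results into one JSON-serializable structure with
#' explicit nulls for absent sections and a provenance block (inputs, seeds,
#' package version, accumulated warnings).
#'
#' @param compound_id Compound label.
#' @param ic50,kinetics,binding,thermo,cd Optional section contents (the
#'   objects returned by the corresponding stage, or `NULL`).
#' @param provenance Named list recording input files and seeds; the package
#'   version is added automatically.
#' @param warnings Character vector of warnings emitted by any stage.
#' @return A `compound_report` list.
#' @export
build_report <- function(compound_id, ic50 = NULL, kinetics = NULL,
                         binding = NULL, thermo = NULL, cd = NULL,
                         provenance = list(), warnings = character(0)) {
  sections <- list(ic50 = ic50, kinetics = kinetics, binding = binding,
                   thermo = thermo, cd = cd)
  if (all(vapply(sections, is.null, logical(1)))) {
    ec_stop("empty_report", "at least one section must be present")
  }
  provenance$package_version <-
    as.character(utils::packageVersion("enzchar"))
  provenance$warnings <- as.list(warnings)
  strip <- function(x) {
    if (is.null(x)) return(NULL)
    round_sig(unclass(x))
  }
  structure(c(list(compound_id = compound_id),
              lapply(sections, strip),
              list(provenance = provenance)),
            class = "compound_report")
}

#' Serialize a compound report to JSON
#'
#' Deterministic output: fixed key order (by construction), numerics at
#' 6 significant digits, no rounding surprises from locale.
#'
#' @param report A [build_report()] result.
#' @param path Output file path; `NULL` returns the JSON string.
#' @return The JSON string, invisibly when written to file.
#' @export
write_report_json <- function(report, path = NULL) {
  json <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path, useBytes = TRUE)
  invisible(json)
}
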