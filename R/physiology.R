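#' CNS physiological parameter sets
#'
#' A `cns_physiology` object holds the full CNS physiological parameter
#' vector for one population: compartment volumes, fluid flows, barrier
#' surface areas, compartment pH values and the phospholipid binding-phase
#' fraction. All internal units are fixed (mL, min, ng, cm2); any unit
#' conversion happens at the I/O boundary.
#'
#' @name cns_physiology
#' @keywords internal
NULL

# numeric scalar fields of a physiology set, with units and sign class
.phys_fields <- tibble::tribble(
  ~name,                  ~units,          ~positive,
  "brain_volume",         "mL",            TRUE,
  "f_ecf",                "fraction",      TRUE,
  "f_icf",                "fraction",      TRUE,
  "v_microvasc",          "mL",            TRUE,
  "f_phospholipid",       "fraction",      TRUE,
  "v_lysosome",           "mL",            TRUE,
  "v_lv",                 "mL",            TRUE,
  "v_tfv",                "mL",            TRUE,
  "v_cm",                 "mL",            TRUE,
  "v_sas",                "mL",            TRUE,
  "q_cbf_norm",           "mL/min/100g",   TRUE,
  "q_cbf_total",          "mL/min",        TRUE,
  "q_ecf_bulk",           "mL/min",        TRUE,
  "q_csf",                "mL/min",        TRUE,
  "sa_bbb",               "cm2",           TRUE,
  "sa_bcsfb",             "cm2",           TRUE,
  "bcsfb_split",          "fraction",      TRUE,
  "sa_cell",              "cm2",           TRUE,
  "sa_lysosome",          "cm2",           TRUE,
  "f_paracellular_bbb",   "relative",      TRUE,
  "f_paracellular_bcsfb", "relative",      TRUE,
  "ph_plasma",            "pH",            TRUE,
  "ph_ecf",               "pH",            TRUE,
  "ph_icf",               "pH",            TRUE,
  "ph_lyso",              "pH",            TRUE,
  "ph_csf",               "pH",            TRUE,
  "brain_density",        "g/mL",          TRUE
)

#' Load (or construct) a CNS physiology set
#'
#' Reads a structured YAML configuration (or the shipped cognitively healthy
#' young adult, CHY, defaults) into a validated `cns_physiology` object.
#' Every field carries a provenance label (`"config"` for user-supplied
#' values, `"literature-default"` for shipped defaults).
#'
#' @param config `NULL` for the shipped CHY defaults, a path to a YAML file
#'   with a top-level `physiology:` section (or flat keys), or a named list
#'   of fields overriding the defaults.
#' @return A `cns_physiology` object (named list of parameters with
#'   `population`, `age` and a per-field `provenance` attribute).
#' @examples
#' chy <- load_physiology()
#' chy$f_ecf
#' @export
load_physiology <- function(config = NULL) {
  defaults <- .read_physiology_yaml(
    system.file("extdata", "physiology_chy.yaml", package = "cnspbpk")
  )
  if (is.null(config)) {
    vals <- defaults
    prov <- stats::setNames(rep("literature-default", length(vals)), names(vals))
    prov[c("f_ecf", "f_icf", "f_phospholipid")] <- "reference-publication"
  } else {
    user <- if (is.character(config)) .read_physiology_yaml(config) else as.list(config)
    unknown <- setdiff(names(user), c(names(defaults), "population", "age"))
    if (length(unknown) > 0) {
      rlang::abort(
        paste0("Unknown physiology field(s): ", paste(unknown, collapse = ", ")),
        class = "cnspbpk_config_error"
      )
    }
    vals <- utils::modifyList(defaults, user)
    prov <- stats::setNames(
      ifelse(names(vals) %in% names(user), "config", "literature-default"),
      names(vals)
    )
  }
  missing <- setdiff(.phys_fields$name, names(vals))
  if (length(missing) > 0) {
    rlang::abort(
      paste0("Missing required physiology field(s): ", paste(missing, collapse = ", ")),
      class = "cnspbpk_config_error"
    )
  }
  p <- new_physiology(vals, provenance = prov)
  report <- validate_physiology(p)
  if (nrow(report) > 0) {
    rlang::abort(
      paste0(
        "Invalid physiology set:\n",
        paste0("- ", report$field, ": ", report$message, collapse = "\n")
      ),
      class = "cnspbpk_validation_error"
    )
  }
  p
}

.read_physiology_yaml <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("Physiology config not found: ", path),
                 class = "cnspbpk_config_error")
  }
  y <- yaml::read_yaml(path)
  if (!is.null(y$physiology)) y <- y$physiology
  y$transporter_activity <- unlist(y$transporter_activity)
  y
}

#' @rdname load_physiology
#' @param vals Named list of physiology fields.
#' @param provenance Optional named character vector of per-field provenance
#'   labels.
#' @export
new_physiology <- function(vals, provenance = NULL) {
  vals$population <- vals$population %||% "CHY"
  vals$age <- vals$age %||% 35
  vals$severity <- vals$severity %||% NA_character_
  if (is.null(provenance)) {
    provenance <- stats::setNames(rep("constructed", length(vals)), names(vals))
  }
  structure(vals, provenance = provenance, class = "cns_physiology")
}

#' Validate a CNS physiology set
#'
#' Checks the structural invariants of a physiology set and reports every
#' violation. Never mutates or errors on its input.
#'
#' @param p A `cns_physiology` object (or compatible named list).
#' @param consistency If `TRUE` (default) also check the cross-field
#'   consistency invariants (ECF/ICF fractions summing to one, total CBF
#'   matching normalised CBF, pH plausibility band). The one-at-a-time
#'   sensitivity analysis disables these, as its perturbations probe the
#'   assembled model rather than a physiologically self-consistent state.
#' @return A tibble with columns `field` and `message`, one row per violated
#'   invariant (zero rows if valid).
#' @export
validate_physiology <- function(p, consistency = TRUE) {
  bad <- list()
  flag <- function(field, message) {
    bad[[length(bad) + 1]] <<- tibble::tibble(field = field, message = message)
  }
  for (i in seq_len(nrow(.phys_fields))) {
    nm <- .phys_fields$name[i]
    v <- p[[nm]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      flag(nm, "missing or non-finite")
    } else if (.phys_fields$positive[i] && v <= 0) {
      flag(nm, "must be strictly positive")
    }
  }
  num_ok <- function(nm) is.numeric(p[[nm]]) && length(p[[nm]]) == 1 && is.finite(p[[nm]])
  if (num_ok("f_ecf") && p$f_ecf >= 1) flag("f_ecf", "must be < 1")
  if (num_ok("f_phospholipid") && p$f_phospholipid >= 1) flag("f_phospholipid", "must be < 1")
  if (num_ok("bcsfb_split") && p$bcsfb_split >= 1) flag("bcsfb_split", "must be < 1")
  ta <- p$transporter_activity
  if (is.null(ta) || !is.numeric(ta) || any(!is.finite(ta)) || any(ta <= 0)) {
    flag("transporter_activity", "must be a named numeric vector of positive activities")
  }
  if (consistency) {
    if (num_ok("f_ecf") && num_ok("f_icf") &&
        abs(p$f_ecf + p$f_icf - 1) > 1e-6) {
      flag("f_icf", "ECF and ICF volume fractions do not sum to 1")
    }
    for (nm in c("ph_plasma", "ph_ecf", "ph_icf", "ph_lyso", "ph_csf")) {
      if (num_ok(nm) && (p[[nm]] < 4 || p[[nm]] > 9)) {
        flag(nm, "pH outside plausibility band [4, 9]")
      }
    }
    if (num_ok("q_cbf_total") && num_ok("q_cbf_norm") &&
        num_ok("brain_volume") && num_ok("brain_density")) {
      expected <- p$q_cbf_norm * p$brain_volume * p$brain_density / 100
      if (abs(p$q_cbf_total - expected) > 1e-3 * expected) {
        flag("q_cbf_total",
             "inconsistent with normalised CBF and brain mass (> 0.1% off)")
      }
    }
  }
  if (length(bad) == 0) {
    tibble::tibble(field = character(), message = character())
  } else {
    dplyr::bind_rows(bad)
  }
}

#' Brain mass implied by a physiology set
#' @param p A `cns_physiology` object.
#' @return Brain mass in grams.
#' @export
brain_mass <- function(p) p$brain_volume * p$brain_density

#' Write a physiology set to a YAML configuration file
#'
#' The written file round-trips: [load_physiology()] on the result recovers
#' field-wise identical values.
#'
#' @param p A `cns_physiology` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_physiology <- function(p, path) {
  vals <- unclass(p)
  attr(vals, "provenance") <- NULL
  vals$transporter_activity <- as.list(vals$transporter_activity)
  vals$severity <- NULL
  yaml::write_yaml(list(physiology = vals), path, precision = 15)
  invisible(path)
}

#' @export
print.cns_physiology <- function(x, ...) {
  cat(sprintf("<cns_physiology> population %s, age %s\n", x$population, x$age))
  cat(sprintf("  brain %0.0f mL (ECF %0.3f / ICF %0.3f), CSF %0.1f mL, q_csf %0.3f mL/min\n",
              x$brain_volume, x$f_ecf, x$f_icf,
              x$v_lv + x$v_tfv + x$v_cm + x$v_sas, x$q_csf))
  invisible(x)
}

#' Tabulate a physiology set
#'
#' @param x A `cns_physiology` object.
#' @param ... Unused.
#' @return A tibble with columns `name`, `value`, `units`, `provenance`,
#'   suitable for CSV export.
#' @method as_tibble cns_physiology
#' @export
as_tibble.cns_physiology <- function(x, ...) {
  prov <- attr(x, "provenance")
  base <- tibble::tibble(
    name = .phys_fields$name,
    value = purrr::map_dbl(.phys_fields$name, ~ x[[.x]]),
    units = .phys_fields$units,
    provenance = unname(prov[.phys_fields$name])
  )
  ta <- x$transporter_activity
  dplyr::bind_rows(base, tibble::tibble(
    name = paste0("transporter_activity.", names(ta)),
    value = unname(ta),
    units = "relative",
    provenance = unname(prov["transporter_activity"])
  ))
}

#' Export a physiology parameter table as CSV
#'
#' @param p A `cns_physiology` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_physiology_csv <- function(p, path) {
  utils::write.csv(as_tibble.cns_physiology(p), path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
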