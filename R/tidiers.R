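#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a CNS model: the calibrated asymmetry factors and achieved ratios
#'
#' @param x A `cns_model`.
#' @param ... Unused.
#' @return A tibble with one row per barrier: asymmetry factors and Kpuu
#'   targets.
#' @method tidy cns_model
#' @export
tidy.cns_model <- function(x, ...) {
  ach <- steady_state_ratios(x)
  dplyr::mutate(x$af, achieved = unname(
    ach[c("brain_ECF", "CSF_LV", "CSF_TFV")]))
}

#' One-row summary of a CNS model
#'
#' @param x A `cns_model`.
#' @param ... Unused.
#' @return A one-row tibble: drug, population, age, effective brain unbound
#'   fraction, total apparent CNS volume and key clearances.
#' @method glance cns_model
#' @export
glance.cns_model <- function(x, ...) {
  tibble::tibble(
    drug = x$drug$name,
    population = x$phys$population,
    age = x$phys$age,
    fu_brain_eff = x$fu_eff,
    v_cns_apparent = sum(x$vap),
    cl_bbb_in = x$clearances$bbb_in,
    cl_bbb_out = x$clearances$bbb_out,
    q_csf = x$phys$q_csf,
    q_ecf_bulk = x$phys$q_ecf_bulk
  )
}

#' Tidy a physiology set into a parameter table
#'
#' @param x A `cns_physiology`.
#' @param ... Unused.
#' @return A tibble: `name`, `value`, `units`, `provenance`.
#' @method tidy cns_physiology
#' @export
tidy.cns_physiology <- function(x, ...) as_tibble.cns_physiology(x)

#' Tidy PK metrics (already tabular; returned as a plain tibble)
#'
#' @param x A `cns_pk_metrics`.
#' @param ... Unused.
#' @method tidy cns_pk_metrics
#' @export
tidy.cns_pk_metrics <- function(x, ...) tibble::as_tibble(unclass(x))

#' Export a clearance table for inspection
#'
#' @param model A `cns_model`.
#' @return A tibble of every clearance and flow term of the assembled system
#'   (mL/min).
#' @export
clearance_table <- function(model) {
  cl <- model$clearances
  tibble::tibble(
    term = c("bbb_in", "bbb_out", "bcsfb_lv_in", "bcsfb_lv_out",
             "bcsfb_tfv_in", "bcsfb_tfv_out", "ecf_icf_fwd", "ecf_icf_back",
             "icf_lyso_fwd", "icf_lyso_back",
             paste0("csf_flow_", names(cl$csf_chain_flow))),
    value = c(cl$bbb_in, cl$bbb_out, cl$bcsfb_lv_in, cl$bcsfb_lv_out,
              cl$bcsfb_tfv_in, cl$bcsfb_tfv_out, cl$ecf_icf_fwd,
              cl$ecf_icf_back, cl$icf_lyso_fwd, cl$icf_lyso_back,
              unname(cl$csf_chain_flow)),
    units = "mL/min"
  )
}

#' Export a tidy concentration profile as CSV
#'
#' Columns `time_min`, `compartment`, `conc_ng_per_ml`.
#'
#' @param profile A `cns_profile`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_profile_csv <- function(profile, path) {
  out <- tibble::tibble(
    time_min = profile$time,
    compartment = profile$compartment,
    conc_ng_per_ml = profile$conc
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
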