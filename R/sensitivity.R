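#' One-at-a-time sensitivity analysis of the assembled CNS model
#'
#' Perturbs single physiological parameters of the chosen population model
#' one at a time — by factors of 2 and 10 up and down for ordinary
#' parameters, and by plus/minus 1 and 2 pH units for the pH fields — and
#' reports the percent change of the steady-state Cmax, Tmax, terminal
#' half-life and AUC at brain ECF, brain ICF and subarachnoid CSF relative
#' to the unperturbed reference. Asymmetry factors are calibrated once on
#' the reference model and held fixed during perturbation (re-calibrating
#' would cancel barrier-level perturbations by construction); set
#' `recalibrate = TRUE` to re-calibrate per perturbation instead.
#'
#' Perturbations that make the physiology structurally invalid (for
#' example an ECF fraction of 1 or more) are recorded as skipped with a
#' reason, not errors. Percent change is `100 * (perturbed - reference) /
#' reference`.
#'
#' @param drug Registry drug name or `cns_drug` record.
#' @param population Population label (default `"AD"`).
#' @param parameters Physiology field names to perturb; default is every
#'   numeric field of the physiology set (pH fields get the pH scheme).
#' @param factors Multiplicative factors (applied with their reciprocals).
#' @param ph_deltas Additive pH perturbations (applied with both signs).
#' @param age Simulation age.
#' @param compartments Compartments to report.
#' @param recalibrate Re-calibrate asymmetry factors for each perturbation.
#' @param ... Passed to [run_to_steady_state()].
#' @return A `cns_sensitivity` tibble sorted by the largest absolute percent
#'   change, with one row per parameter, perturbation and compartment, and a
#'   `skipped`/`reason` pair for invalid perturbations.
#' @export
oat_sensitivity <- function(drug, population = "AD", parameters = NULL,
                            factors = c(2, 10), ph_deltas = c(1, 2),
                            age = NULL,
                            compartments = c("brain_ECF", "brain_ICF",
                                             "CSF_SAS"),
                            recalibrate = FALSE, ...) {
  d <- if (inherits(drug, "cns_drug")) drug else load_drug(drug)
  p0 <- build_population(population, age = age)
  ref_model <- build_model(p0, d)
  ref_prof <- run_to_steady_state(ref_model, ...)
  ref_met <- compute_metrics(ref_prof, compartments)

  ph_fields <- c("ph_plasma", "ph_ecf", "ph_icf", "ph_lyso", "ph_csf")
  parameters <- parameters %||%
    setdiff(.phys_fields$name, character(0))

  perturbations <- purrr::map_dfr(parameters, function(nm) {
    if (nm %in% ph_fields) {
      tibble::tibble(parameter = nm,
                     perturbation = c(ph_deltas, -ph_deltas),
                     kind = "ph_shift")
    } else {
      tibble::tibble(parameter = nm,
                     perturbation = c(factors, 1 / factors),
                     kind = "factor")
    }
  })

  rows <- purrr::pmap(perturbations, function(parameter, perturbation, kind) {
    p2 <- p0
    p2[[parameter]] <- if (kind == "ph_shift") {
      p0[[parameter]] + perturbation
    } else {
      p0[[parameter]] * perturbation
    }
    bad <- .sensitivity_invalid(p2, parameter)
    base_row <- tibble::tibble(parameter = parameter,
                               perturbation = perturbation, kind = kind)
    if (!is.null(bad)) {
      return(dplyr::mutate(base_row, compartment = NA_character_,
                           skipped = TRUE, reason = bad))
    }
    af <- if (recalibrate) NULL else ref_model$af
    met <- tryCatch({
      mod <- build_model(p2, d, af = af)
      compute_metrics(run_to_steady_state(mod, ...), compartments)
    }, error = function(e) e)
    if (inherits(met, "error")) {
      return(dplyr::mutate(base_row, compartment = NA_character_,
                           skipped = TRUE, reason = conditionMessage(met)))
    }
    pc <- function(new, old) 100 * (new - old) / old
    purrr::map_dfr(compartments, function(cc) {
      m2 <- met[met$compartment == cc, ]
      m1 <- ref_met[ref_met$compartment == cc, ]
      dplyr::mutate(base_row, compartment = cc, skipped = FALSE,
                    reason = NA_character_,
                    cmax_pct = pc(m2$cmax, m1$cmax),
                    tmax_pct = pc(m2$tmax, m1$tmax),
                    half_life_pct = pc(m2$half_life, m1$half_life),
                    auc_pct = pc(m2$auc_tau, m1$auc_tau))
    })
  })
  out <- dplyr::bind_rows(rows)
  score <- out |>
    dplyr::filter(!.data$skipped) |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(rank_score = max(abs(c(.data$cmax_pct, .data$auc_pct)),
                                      na.rm = TRUE), .groups = "drop")
  out <- dplyr::left_join(out, score, by = "parameter") |>
    dplyr::arrange(dplyr::desc(.data$rank_score))
  class(out) <- c("cns_sensitivity", class(out))
  attr(out, "reference") <- ref_met
  out
}

# structural validity only: perturbations probe the assembled model, so the
# loader's physiological-consistency invariants do not apply here
.sensitivity_invalid <- function(p, parameter) {
  v <- p[[parameter]]
  if (!is.finite(v)) return("non-finite value")
  if (!startsWith(parameter, "ph_") && v <= 0) return("non-positive value")
  if (parameter %in% c("f_ecf", "f_icf", "f_phospholipid", "bcsfb_split") &&
      v >= 1) {
    return("fraction >= 1")
  }
  NULL
}
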