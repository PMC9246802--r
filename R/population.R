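#' Aging rates for translating CHY physiology to the elderly
#'
#' Per-year percentage rates and one-time senescence totals describing how
#' CNS physiology changes with healthy aging from the onset age (60 years)
#' onwards. Per-year rates compound multiplicatively,
#' `value(age) = value(60) * (1 +/- r/100)^(age - 60)`; a linear alternative
#' is available via `compounding = FALSE`. Totals reported for the elderly
#' population as a whole (ECF fraction, ECF bulk flow, BBB surface area) are
#' phased in linearly over `senescence_span` years so that physiology is
#' continuous at the onset age.
#'
#' @param brain_shrinkage_rate Brain volume shrinkage, percent/year.
#' @param ventricle_expansion_rate Lateral and third+fourth ventricle
#'   expansion, percent/year.
#' @param cm_expansion_rate Cisterna magna expansion, percent/year.
#' @param sas_expansion_rate Subarachnoid CSF expansion, percent/year.
#' @param ecf_fraction_change Total percent change of the brain ECF volume
#'   fraction over senescence (negative = decrease).
#' @param phospholipid_decline_60_80,phospholipid_decline_80_100 Percent
#'   decline of the phospholipid volume fraction over ages 60-80 and the
#'   further decline over 80-100 (piecewise linear within each band).
#' @param ecf_bulk_flow_decline Total percent decline of brain ECF bulk flow
#'   over senescence (applied before brain-atrophy correction).
#' @param bbb_sa_decline Total percent decline of BBB surface area over
#'   senescence, on top of atrophy correction.
#' @param icf_ph_drift Brain ICF pH drift, pH units/year (negative).
#' @param onset_age Age (years) at which aging changes start.
#' @param senescence_span Years over which one-time senescence totals are
#'   phased in.
#' @param compounding Compound per-year rates multiplicatively (default) or
#'   apply them linearly.
#' @return An `aging_rates` parameter object.
#' @export
aging_rates <- function(brain_shrinkage_rate = 0.401,
                        ventricle_expansion_rate = 3.45,
                        cm_expansion_rate = 1.09,
                        sas_expansion_rate = 0.78,
                        ecf_fraction_change = -16,
                        phospholipid_decline_60_80 = 10,
                        phospholipid_decline_80_100 = 8,
                        ecf_bulk_flow_decline = 33,
                        bbb_sa_decline = 10,
                        icf_ph_drift = -0.001,
                        onset_age = 60,
                        senescence_span = 20,
                        compounding = TRUE) {
  r <- as.list(environment())
  stopifnot(all(vapply(r[setdiff(names(r), "compounding")], is.numeric, TRUE)))
  if (onset_age < 0) rlang::abort("onset_age must be >= 0", class = "cnspbpk_domain_error")
  structure(r, class = "aging_rates")
}

#' Alzheimer's-disease fold changes relative to age-matched elderly
#'
#' Dimensionless multipliers (and one pH shift) applied to an elderly (CHE)
#' physiology set to obtain a mild Alzheimer's (AD) set. All factors are
#' CHE-relative and therefore not composable: applying them twice is an
#' error.
#'
#' @param brain_volume_factor Brain volume multiplier (atrophy beyond aging).
#' @param ecf_fraction_factor Brain ECF volume-fraction multiplier.
#' @param phospholipid_factor Phospholipid volume-fraction multiplier.
#' @param ventricle_factor Lateral and third+fourth ventricle volume multiplier.
#' @param extraventricular_factor Cisterna magna and subarachnoid CSF volume
#'   multiplier.
#' @param cbf_norm_factor Normalised cerebral blood flow multiplier.
#' @param ecf_bulk_flow_factor Brain ECF bulk-flow multiplier (before atrophy
#'   correction).
#' @param bbb_sa_factor BBB surface-area multiplier (after atrophy correction).
#' @param bbb_paracellular_factor BBB paracellular-permeability multiplier.
#' @param bcsfb_paracellular_factor BCSFB paracellular-permeability multiplier.
#' @param transporter_factors Named multipliers on transporter-class activity.
#' @param lumbar_csf_ph_shift Additive shift of the CSF pH (pH units).
#' @param brain_ph_shift Additive shift of brain ECF/ICF pH (pH units); the
#'   reported range is 0 to +0.009 with no single consensus value, so the
#'   default is 0.
#' @return An `ad_fold_changes` parameter object.
#' @export
ad_fold_changes <- function(brain_volume_factor = 0.95,
                            ecf_fraction_factor = 1.4,
                            phospholipid_factor = 0.90,
                            ventricle_factor = 1.39,
                            extraventricular_factor = 1.21,
                            cbf_norm_factor = 0.85,
                            ecf_bulk_flow_factor = 0.85,
                            bbb_sa_factor = 1.1123,
                            bbb_paracellular_factor = 4.4,
                            bcsfb_paracellular_factor = 1.0,
                            transporter_factors = c(pgp = 1, bcrp = 1,
                                                    cht = 1, octn1 = 1),
                            lumbar_csf_ph_shift = 0.018,
                            brain_ph_shift = 0) {
  f <- as.list(environment())
  mult <- unlist(f[!names(f) %in% c("lumbar_csf_ph_shift", "brain_ph_shift")])
  if (any(!is.finite(mult)) || any(mult <= 0)) {
    rlang::abort("All AD fold-change multipliers must be positive and finite",
                 class = "cnspbpk_validation_error")
  }
  structure(f, class = "ad_fold_changes")
}

#' Age a CHY physiology set into a cognitively healthy elderly (CHE) set
#'
#' Applies the aging rates to every affected parameter: brain volume shrinks
#' and CSF spaces expand by compounded per-year rates; the phospholipid
#' fraction declines piecewise-linearly across the 60-80 and 80-100 bands;
#' ECF bulk flow and BBB surface area take their senescence declines plus a
#' brain-atrophy correction; total CBF is recomputed from the unchanged
#' normalised CBF on the shrunken brain; microvascular volume preserves the
#' young microvascular-volume:CBF ratio; brain ICF pH drifts down. CSF flow,
#' ECF/CSF pH, paracellular factors and transporter activities are
#' unchanged.
#'
#' @param p A `cns_physiology` set (CHY reference).
#' @param age Target age in years (>= 0). Ages at or below the onset age
#'   return the input values unchanged.
#' @param rates An [aging_rates()] object.
#' @return A new `cns_physiology` set labelled CHE.
#' @export
apply_aging <- function(p, age, rates = aging_rates()) {
  if (!is.numeric(age) || length(age) != 1 || !is.finite(age) || age < 0) {
    rlang::abort("age must be a single non-negative number",
                 class = "cnspbpk_domain_error")
  }
  out <- p
  out$age <- age
  if (age <= rates$onset_age) {
    return(out)
  }
  out$population <- "CHE"
  yrs <- age - rates$onset_age
  comp <- function(value, rate_pct) {
    if (isTRUE(rates$compounding)) value * (1 + rate_pct / 100)^yrs
    else value * (1 + rate_pct * yrs / 100)
  }
  ramp <- min(1, yrs / rates$senescence_span)

  out$brain_volume <- comp(p$brain_volume, -rates$brain_shrinkage_rate)
  atrophy <- out$brain_volume / p$brain_volume
  out$v_lv <- comp(p$v_lv, rates$ventricle_expansion_rate)
  out$v_tfv <- comp(p$v_tfv, rates$ventricle_expansion_rate)
  out$v_cm <- comp(p$v_cm, rates$cm_expansion_rate)
  out$v_sas <- comp(p$v_sas, rates$sas_expansion_rate)

  out$f_ecf <- p$f_ecf * (1 + rates$ecf_fraction_change / 100 * ramp)
  out$f_icf <- 1 - out$f_ecf

  # biphasic phospholipid decline: -10% by 80, a further -8% by 100
  band1 <- min(yrs, 20) / 20
  band2 <- min(max(yrs - 20, 0), 20) / 20
  out$f_phospholipid <- p$f_phospholipid *
    (1 - rates$phospholipid_decline_60_80 / 100 * band1) *
    (1 - rates$phospholipid_decline_80_100 / 100 * band2)

  out$q_ecf_bulk <- p$q_ecf_bulk *
    (1 - rates$ecf_bulk_flow_decline / 100 * ramp) * atrophy
  out$sa_bbb <- p$sa_bbb * atrophy * (1 - rates$bbb_sa_decline / 100 * ramp)
  out$sa_cell <- p$sa_cell * atrophy

  out$q_cbf_total <- p$q_cbf_norm * brain_mass(out) / 100
  out$v_microvasc <- p$v_microvasc / p$q_cbf_total * out$q_cbf_total
  out$ph_icf <- p$ph_icf + rates$icf_ph_drift * yrs
  out
}

#' Translate an elderly (CHE) physiology set to mild Alzheimer's (AD)
#'
#' Applies the CHE-relative AD fold changes: additional brain atrophy, ECF
#' fraction expansion (with ICF as its complement), phospholipid loss,
#' ventricular and extraventricular CSF expansion, reduced normalised CBF
#' and ECF bulk flow (both atrophy-corrected), increased BBB surface area
#' and paracellular permeability, and the lumbar CSF pH shift. CSF flow and
#' BCSFB paracellular transport are unchanged.
#'
#' @param p A `cns_physiology` set labelled CHE (aged with [apply_aging()]).
#' @param folds An [ad_fold_changes()] object.
#' @return A new `cns_physiology` set labelled AD (mild severity).
#' @export
apply_ad <- function(p, folds = ad_fold_changes()) {
  if (identical(p$population, "AD")) {
    rlang::abort(
      "Physiology is already an AD set: AD fold changes are CHE-relative and not composable",
      class = "cnspbpk_domain_error"
    )
  }
  if (!identical(p$population, "CHE")) {
    rlang::warn("apply_ad() expects an age-matched CHE set; applying to a non-CHE set")
  }
  out <- p
  out$population <- "AD"
  out$severity <- "mild"

  out$brain_volume <- p$brain_volume * folds$brain_volume_factor
  atrophy <- folds$brain_volume_factor
  out$f_ecf <- p$f_ecf * folds$ecf_fraction_factor
  if (out$f_ecf >= 1) {
    rlang::abort("AD ECF fraction factor drives f_ecf to >= 1",
                 class = "cnspbpk_validation_error")
  }
  out$f_icf <- 1 - out$f_ecf
  out$f_phospholipid <- p$f_phospholipid * folds$phospholipid_factor
  out$v_lv <- p$v_lv * folds$ventricle_factor
  out$v_tfv <- p$v_tfv * folds$ventricle_factor
  out$v_cm <- p$v_cm * folds$extraventricular_factor
  out$v_sas <- p$v_sas * folds$extraventricular_factor

  out$q_cbf_norm <- p$q_cbf_norm * folds$cbf_norm_factor
  out$q_cbf_total <- out$q_cbf_norm * brain_mass(out) / 100
  out$v_microvasc <- p$v_microvasc / p$q_cbf_total * out$q_cbf_total
  out$q_ecf_bulk <- p$q_ecf_bulk * folds$ecf_bulk_flow_factor * atrophy
  out$sa_bbb <- p$sa_bbb * atrophy * folds$bbb_sa_factor
  out$sa_cell <- p$sa_cell * atrophy
  out$f_paracellular_bbb <- p$f_paracellular_bbb * folds$bbb_paracellular_factor
  out$f_paracellular_bcsfb <- p$f_paracellular_bcsfb * folds$bcsfb_paracellular_factor
  tf <- folds$transporter_factors
  common <- intersect(names(out$transporter_activity), names(tf))
  out$transporter_activity[common] <- out$transporter_activity[common] * tf[common]
  out$ph_csf <- p$ph_csf + folds$lumbar_csf_ph_shift
  out$ph_ecf <- p$ph_ecf + folds$brain_ph_shift
  out$ph_icf <- p$ph_icf + folds$brain_ph_shift
  out
}

#' Build a population physiology set by label
#'
#' Dispatches the identity (CHY), aging (CHE) or aging-plus-AD translation
#' and validates the result. Only mild AD is parameterised; requesting
#' another severity is an explicit error.
#'
#' @param label One of `"CHY"`, `"CHE"`, `"AD"` (case-insensitive).
#' @param base The CHY reference physiology (defaults to the shipped set).
#' @param age Simulation age in years; defaults to 35 for CHY and 70 for
#'   CHE/AD (age-matched).
#' @param rates,folds Translation parameter objects.
#' @param severity AD severity label; only `"mild"` is supported.
#' @return A validated `cns_physiology` set.
#' @examples
#' ad <- build_population("AD", age = 70)
#' ad$f_paracellular_bbb
#' @export
build_population <- function(label,
                             base = load_physiology(),
                             age = NULL,
                             rates = aging_rates(),
                             folds = ad_fold_changes(),
                             severity = "mild") {
  label <- toupper(label)
  if (!label %in% c("CHY", "CHE", "AD")) {
    rlang::abort("Population label must be one of CHY, CHE, AD",
                 class = "cnspbpk_domain_error")
  }
  if (label == "AD" && !identical(severity, "mild")) {
    rlang::abort(
      paste0("Unsupported AD severity '", severity,
             "': only the mild AD population is parameterised"),
      class = "cnspbpk_domain_error"
    )
  }
  age <- age %||% if (label == "CHY") 35 else 70
  out <- switch(label,
    CHY = { b <- base; b$age <- age; b },
    CHE = apply_aging(base, age, rates),
    AD = apply_ad(apply_aging(base, age, rates), folds)
  )
  report <- validate_physiology(out)
  if (nrow(report) > 0) {
    rlang::abort(
      paste0("Translated physiology failed validation:\n",
             paste0("- ", report$field, ": ", report$message, collapse = "\n")),
      class = "cnspbpk_validation_error"
    )
  }
  out
}
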