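#' Load a drug parameter record
#'
#' Returns the physicochemical and biological parameters of a drug from the
#' shipped registry (donepezil, galantamine, memantine, rivastigmine,
#' semagacestat), or constructs one from a full configuration list. The
#' record bundles the unbound plasma PK model and clinical dosing regimen
#' for registry drugs.
#'
#' @param name Registry drug name (case-insensitive), or `NULL` when `config`
#'   is given.
#' @param config Optional named list with the fields of a drug record
#'   (`name`, `mw`, `logp`, `pka_acid`, `pka_base`, `fu_p`, `fu_b`,
#'   `kpuu_bbb`, `kpuu_lv`, `kpuu_lumbar`, `ic50_unbound`, ...).
#' @return A `cns_drug` object. Registry records carry `$plasma`
#'   ([plasma_model()]) and `$regimen` ([dose_regimen()]) components.
#' @examples
#' mem <- load_drug("memantine")
#' mem$kpuu_bbb
#' @export
load_drug <- function(name = NULL, config = NULL) {
  if (is.null(config)) {
    reg <- .drug_registry()
    key <- tolower(name %||% "")
    if (!key %in% names(reg)) {
      rlang::abort(
        paste0("Unknown drug '", name, "'. Shipped registry: ",
               paste(names(reg), collapse = ", "),
               ". Pass a full config for other drugs."),
        class = "cnspbpk_lookup_error"
      )
    }
    config <- reg[[key]]
    config$name <- key
  } else {
    config <- as.list(config)
    config$name <- config$name %||% name %||% "custom"
  }
  new_drug(config)
}

.drug_registry <- function() {
  path <- system.file("extdata", "drug_registry.yaml", package = "cnspbpk")
  yaml::read_yaml(path)
}

#' @rdname load_drug
#' @export
new_drug <- function(config) {
  d <- list(
    name = config$name,
    mw = config$mw,
    logp = config$logp,
    pka_acid = .na_num(config$pka_acid),
    pka_base = .na_num(config$pka_base),
    fu_p = config$fu_p,
    fu_b = config$fu_b,
    kpuu_bbb = config$kpuu_bbb,
    kpuu_bbb_species = config$kpuu_bbb_species %||% "human",
    kpuu_lv = config$kpuu_lv,
    kpuu_lumbar = config$kpuu_lumbar,
    ic50_unbound = config$ic50_unbound,
    ic50_secondary = .na_num(config$ic50_secondary),
    target = config$target %||% NA_character_,
    transporter_substrate = as.character(unlist(config$transporter_substrate)),
    species_scaling = unlist(config$species_scaling) %||% stats::setNames(numeric(0), character(0))
  )
  if (!is.null(config$plasma)) d$plasma <- do.call(plasma_model, config$plasma)
  if (!is.null(config$regimen)) d$regimen <- do.call(dose_regimen, config$regimen)
  d <- structure(d, class = "cns_drug")
  .validate_drug(d)
  d
}

.na_num <- function(x) if (is.null(x) || is.na(x)) NA_real_ else as.numeric(x)

.validate_drug <- function(d) {
  chk <- function(cond, msg) {
    if (!cond) rlang::abort(paste0("Invalid drug record '", d$name, "': ", msg),
                            class = "cnspbpk_validation_error")
  }
  chk(is.numeric(d$mw) && d$mw > 0, "mw must be > 0")
  chk(is.numeric(d$logp) && is.finite(d$logp), "logp must be finite")
  chk(is.numeric(d$fu_p) && d$fu_p > 0 && d$fu_p <= 1, "fu_p must be in (0, 1]")
  chk(is.numeric(d$fu_b) && d$fu_b > 0 && d$fu_b <= 1, "fu_b must be in (0, 1]")
  for (nm in c("kpuu_bbb", "kpuu_lv", "kpuu_lumbar")) {
    chk(is.numeric(d[[nm]]) && d[[nm]] > 0, paste0(nm, " must be > 0"))
  }
  chk(is.numeric(d$ic50_unbound) && d$ic50_unbound > 0, "ic50_unbound must be > 0")
  invisible(d)
}

#' @export
print.cns_drug <- function(x, ...) {
  cat(sprintf("<cns_drug> %s: MW %.1f, logP %.2f, fu_p %.3f, fu_b %.3f\n",
              x$name, x$mw, x$logp, x$fu_p, x$fu_b))
  cat(sprintf("  Kpuu BBB %.3g (%s), LV %.3g, lumbar %.3g; IC50 %.3g ng/mL\n",
              x$kpuu_bbb, x$kpuu_bbb_species, x$kpuu_lv, x$kpuu_lumbar,
              x$ic50_unbound))
  invisible(x)
}

#' Export the drug registry as a tibble / CSV
#'
#' @return A tibble with one row per registry drug.
#' @export
drug_registry_table <- function() {
  reg <- .drug_registry()
  purrr::map_dfr(names(reg), function(nm) {
    d <- load_drug(nm)
    tibble::tibble(
      name = d$name, mw = d$mw, logp = d$logp,
      pka_acid = d$pka_acid, pka_base = d$pka_base,
      fu_p = d$fu_p, fu_b = d$fu_b,
      kpuu_bbb = d$kpuu_bbb, kpuu_bbb_species = d$kpuu_bbb_species,
      kpuu_lv = d$kpuu_lv, kpuu_lumbar = d$kpuu_lumbar,
      ic50_unbound = d$ic50_unbound, ic50_secondary = d$ic50_secondary,
      target = d$target,
      dose_mg = d$regimen$dose, interval_min = d$regimen$interval
    )
  })
}

#' Fraction of drug in the neutral (un-ionised) species at a given pH
#'
#' Henderson-Hasselbalch partitioning for at most one acidic and one basic
#' group: `1 / (1 + 10^(pka_base - pH))` for a monoprotic base,
#' `1 / (1 + 10^(pH - pka_acid))` for a monoprotic acid, their product for an
#' ampholyte, and 1 for a drug with no ionisable group.
#'
#' @param ph pH value(s) in `[0, 14]` (vectorised).
#' @param drug A `cns_drug` record (fields `pka_acid`, `pka_base`; `NA` means
#'   no such group).
#' @return Neutral fraction(s) in `(0, 1]`.
#' @examples
#' fraction_neutral(7.4, load_drug("memantine"))  # strong base: ~5e-4
#' @export
fraction_neutral <- function(ph, drug) {
  stopifnot(all(ph >= 0 & ph <= 14))
  f <- rep(1, length(ph))
  if (!is.na(drug$pka_base)) f <- f / (1 + 10^(drug$pka_base - ph))
  if (!is.na(drug$pka_acid)) f <- f / (1 + 10^(ph - drug$pka_acid))
  f
}

#' Convert a total brain-to-plasma ratio (Kp) to an unbound Kpuu
#'
#' Corrects a total (homogenate) brain:plasma concentration ratio for plasma
#' protein binding, brain tissue binding, and the unequal distribution of
#' ionised drug between brain ECF and ICF driven by their pH difference:
#' `Kpuu = Kp * (fu_b / fu_p) / D` with
#' `D = f_ecf + f_icf * R` and `R = f_neutral(ph_ecf) / f_neutral(ph_icf)`
#' (pH-partition equilibrium of unbound drug between ECF and ICF).
#'
#' @param kp_total Total brain:plasma concentration ratio (> 0).
#' @param drug A `cns_drug` record (needs `fu_p`, `fu_b`, ionisation).
#' @param phys A `cns_physiology` set (needs `f_ecf`, `f_icf`, `ph_ecf`,
#'   `ph_icf`).
#' @return The unbound partition coefficient Kpuu at the BBB.
#' @export
kp_to_kpuu <- function(kp_total, drug, phys) {
  stopifnot(is.numeric(kp_total), all(kp_total > 0))
  if (is.na(drug$fu_b) || is.na(drug$fu_p)) {
    rlang::abort("kp_to_kpuu requires both fu_b and fu_p",
                 class = "cnspbpk_parameterization_error")
  }
  r_icf_ecf <- fraction_neutral(phys$ph_ecf, drug) / fraction_neutral(phys$ph_icf, drug)
  d_factor <- phys$f_ecf + phys$f_icf * r_icf_ecf
  kp_total * (drug$fu_b / drug$fu_p) / d_factor
}

#' Translate a rat asymmetry factor to human via transporter expression
#'
#' An asymmetry factor (AF) is a directional multiplier >= 1 on transcellular
#' barrier clearance encoding net active transport. Cross-species
#' translation multiplies the directional magnitude by the product of the
#' applicable human:rat transporter expression ratios; if the scaled
#' magnitude drops below 1 the net direction flips and the magnitude is
#' reciprocated, keeping the >= 1 reporting convention.
#'
#' @param af Asymmetry factor magnitude (>= 1).
#' @param direction `"influx"` or `"efflux"`.
#' @param scaling Named numeric vector of human:rat expression ratios for the
#'   transporters the drug is a substrate of (empty = no change).
#' @return A list with elements `af` (magnitude >= 1) and `direction`.
#' @examples
#' scale_asymmetry_species(1 / 0.482, "efflux", c(pgp = 0.22, bcrp = 1.1))
#' @export
scale_asymmetry_species <- function(af, direction = c("influx", "efflux"),
                                    scaling = numeric(0)) {
  direction <- match.arg(direction)
  if (!is.numeric(af) || af < 1) {
    rlang::abort("af must be a magnitude >= 1", class = "cnspbpk_domain_error")
  }
  if (length(scaling) > 0 && (any(!is.finite(scaling)) || any(scaling <= 0))) {
    rlang::abort("species scaling ratios must be positive and finite",
                 class = "cnspbpk_domain_error")
  }
  mag <- af * prod(scaling)
  if (mag < 1) {
    direction <- if (direction == "efflux") "influx" else "efflux"
    mag <- 1 / mag
  }
  list(af = mag, direction = direction)
}

#' Helper: unbound IC50 from a total IC50 and brain binding
#'
#' The shipped registry IC50 values are already on the unbound scale; this
#' helper is for parameterising new drugs from total in-vitro potencies.
#'
#' @param ic50_total Total IC50 (ng/mL).
#' @param fu_b Unbound fraction in brain.
#' @return Unbound IC50 (ng/mL).
#' @export
ic50_unbound_from_total <- function(ic50_total, fu_b) {
  stopifnot(ic50_total > 0, fu_b > 0, fu_b <= 1)
  ic50_total * fu_b
}
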