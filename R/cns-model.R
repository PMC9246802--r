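#' Transport parameter map for passive barrier permeabilities
#'
#' The governing mass-balance system uses two passive permeability maps:
#' an aqueous paracellular route with cube-root molecular-weight diffusion
#' scaling, `P_para = p_para_ref * (mw_ref / MW)^(1/3)`, and a log-linear
#' lipophilicity map for the transcellular route carried by the neutral
#' species, `log10 P_trans = p_trans_intercept + p_trans_slope * logP`
#' (cm/min at the reference molecular weight), with the same cube-root MW
#' scaling. The defaults put a logP 2 drug at ~1.3e-5 cm/s, the middle of
#' the passive BBB permeability range; asymmetry-factor calibration absorbs
#' barrier-level error in steady-state ratios by construction, while
#' absolute equilibration rates remain sensitive to this map.
#'
#' @param p_trans_intercept,p_trans_slope Coefficients of the log10
#'   transcellular permeability map (cm/min scale).
#' @param p_para_ref Paracellular permeability at `mw_ref`, cm/min
#'   (default 1e-8 cm/s).
#' @param mw_ref Reference molecular weight, g/mol.
#' @return A `cns_transport_params` object.
#' @export
transport_params <- function(p_trans_intercept = -4.0,
                             p_trans_slope = 0.45,
                             p_para_ref = 6e-7,
                             mw_ref = 350) {
  structure(as.list(environment()), class = "cns_transport_params")
}

#' Passive barrier and membrane clearances
#'
#' Computes the paracellular and transcellular clearance terms (mL/min) for
#' the BBB, the two BCSFB faces (lateral-ventricle and third/fourth-
#' ventricle), the brain cell membrane (ECF-ICF) and the lysosomal membrane.
#' Paracellular clearance scales with the population's relative paracellular
#' permeability multipliers; transcellular clearances are the permeability-
#' surface-area products, to be carried by the neutral fraction on each
#' donor side.
#'
#' @param p A `cns_physiology` set.
#' @param d A `cns_drug` record.
#' @param tp A [transport_params()] object.
#' @return A named list of clearances (mL/min).
#' @export
passive_clearances <- function(p, d, tp = transport_params()) {
  mw_scale <- (tp$mw_ref / d$mw)^(1 / 3)
  p_para <- tp$p_para_ref * mw_scale
  p_trans <- 10^(tp$p_trans_intercept + tp$p_trans_slope * d$logp) * mw_scale
  sa_lv <- p$sa_bcsfb * p$bcsfb_split
  sa_tfv <- p$sa_bcsfb * (1 - p$bcsfb_split)
  list(
    p_para = p_para, p_trans = p_trans,
    cl_para_bbb = p$f_paracellular_bbb * p_para * p$sa_bbb,
    cl_trans_bbb = p_trans * p$sa_bbb,
    cl_para_bcsfb_lv = p$f_paracellular_bcsfb * p_para * sa_lv,
    cl_trans_bcsfb_lv = p_trans * sa_lv,
    cl_para_bcsfb_tfv = p$f_paracellular_bcsfb * p_para * sa_tfv,
    cl_trans_bcsfb_tfv = p_trans * sa_tfv,
    cl_mem_ecf_icf = p_trans * p$sa_cell,
    cl_mem_icf_lyso = p_trans * p$sa_lysosome
  )
}

#' Effective unbound fraction in brain tissue for a population
#'
#' Nonspecific brain binding is attributed to the phospholipid phase, so the
#' bound:unbound capacity scales with the phospholipid volume fraction:
#' `fu_eff = 1 / (1 + (1/fu_b - 1) * f_phospholipid / f_ref)` where `f_ref`
#' is the reference (CHY) phospholipid fraction at which `fu_b` was
#' measured.
#'
#' @param d A `cns_drug` record.
#' @param p A `cns_physiology` set.
#' @param f_phospholipid_ref Reference phospholipid fraction (default 0.05).
#' @return Effective unbound fraction in brain tissue.
#' @export
fu_brain_effective <- function(d, p, f_phospholipid_ref = 0.05) {
  1 / (1 + (1 / d$fu_b - 1) * p$f_phospholipid / f_phospholipid_ref)
}

.cns_compartments <- c("brain_microvascular", "brain_ECF", "brain_ICF",
                       "lysosome", "CSF_LV", "CSF_TFV", "CSF_CM", "CSF_SAS")

# Assemble the linear mass-balance system dA/dt = M A + b * Cp(t), amounts in
# ng. theta_* are net asymmetry parameters (> 1 net influx, < 1 net efflux):
# AF_in = max(theta, 1), AF_ef = max(1/theta, 1).
.assemble_system <- function(p, d, cl, theta_bbb = 1, theta_lv = 1,
                             theta_tfv = 1, bulk_route = "CSF_LV",
                             csf_sink = TRUE) {
  fn_pl <- fraction_neutral(p$ph_plasma, d)
  fn_ecf <- fraction_neutral(p$ph_ecf, d)
  fn_icf <- fraction_neutral(p$ph_icf, d)
  fn_lyso <- fraction_neutral(p$ph_lyso, d)
  fn_csf <- fraction_neutral(p$ph_csf, d)
  fu_eff <- fu_brain_effective(d, p)

  v_ecf <- p$brain_volume * p$f_ecf
  v_icf <- p$brain_volume * p$f_icf
  vap <- c(
    brain_microvascular = p$v_microvasc,
    brain_ECF = v_ecf,
    brain_ICF = v_icf / fu_eff,
    lysosome = p$v_lysosome / fu_eff,
    CSF_LV = p$v_lv, CSF_TFV = p$v_tfv, CSF_CM = p$v_cm, CSF_SAS = p$v_sas
  )

  af <- function(theta) c(inn = max(theta, 1), eff = max(1 / theta, 1))
  a_bbb <- af(theta_bbb); a_lv <- af(theta_lv); a_tfv <- af(theta_tfv)

  # conc-space exchange coefficients (mL/min)
  bbb_in <- cl$cl_para_bbb + cl$cl_trans_bbb * a_bbb["inn"] * fn_pl
  bbb_out <- cl$cl_para_bbb + cl$cl_trans_bbb * a_bbb["eff"] * fn_ecf
  lv_in <- cl$cl_para_bcsfb_lv + cl$cl_trans_bcsfb_lv * a_lv["inn"] * fn_pl
  lv_out <- cl$cl_para_bcsfb_lv + cl$cl_trans_bcsfb_lv * a_lv["eff"] * fn_csf
  tfv_in <- cl$cl_para_bcsfb_tfv + cl$cl_trans_bcsfb_tfv * a_tfv["inn"] * fn_pl
  tfv_out <- cl$cl_para_bcsfb_tfv + cl$cl_trans_bcsfb_tfv * a_tfv["eff"] * fn_csf
  ei_f <- cl$cl_mem_ecf_icf * fn_ecf
  ei_b <- cl$cl_mem_ecf_icf * fn_icf
  il_f <- cl$cl_mem_icf_lyso * fn_icf
  il_b <- cl$cl_mem_icf_lyso * fn_lyso

  # CSF chain flow: the produced q_csf runs the whole chain; the ECF bulk
  # flow joins at its entry compartment and is carried downstream
  # (fluid conservation).
  q <- p$q_csf
  qb <- p$q_ecf_bulk
  seg_after <- function(comp) {
    entry <- match(bulk_route, c("CSF_LV", "CSF_TFV", "CSF_CM", "CSF_SAS"))
    here <- match(comp, c("CSF_LV", "CSF_TFV", "CSF_CM", "CSF_SAS"))
    q + if (here >= entry) qb else 0
  }
  flow_lv <- seg_after("CSF_LV")    # LV -> TFV
  flow_tfv <- seg_after("CSF_TFV")  # TFV -> CM
  flow_cm <- seg_after("CSF_CM")    # CM -> SAS
  flow_sas <- seg_after("CSF_SAS")  # SAS -> sink

  n <- length(.cns_compartments)
  K <- matrix(0, n, n, dimnames = list(.cns_compartments, .cns_compartments))
  K["brain_ECF", "brain_microvascular"] <- bbb_in
  K["brain_microvascular", "brain_ECF"] <- bbb_out
  K["brain_ICF", "brain_ECF"] <- ei_f
  K["brain_ECF", "brain_ICF"] <- ei_b
  K["lysosome", "brain_ICF"] <- il_f
  K["brain_ICF", "lysosome"] <- il_b
  K["CSF_TFV", "CSF_LV"] <- flow_lv
  K["CSF_CM", "CSF_TFV"] <- flow_tfv
  K["CSF_SAS", "CSF_CM"] <- flow_cm
  K[bulk_route, "brain_ECF"] <- K[bulk_route, "brain_ECF"] + qb

  outflow <- c(
    brain_microvascular = unname(p$q_cbf_total + bbb_in),
    brain_ECF = unname(bbb_out + ei_f + qb),
    brain_ICF = unname(ei_b + il_f),
    lysosome = unname(il_b),
    CSF_LV = unname(lv_out + flow_lv),
    CSF_TFV = unname(tfv_out + flow_tfv),
    CSF_CM = unname(flow_cm),
    CSF_SAS = unname(if (csf_sink) flow_sas else 0)
  )

  M <- K - diag(outflow)
  M <- sweep(M, 2, vap, "/")
  b <- c(brain_microvascular = unname(p$q_cbf_total),
         brain_ECF = 0, brain_ICF = 0, lysosome = 0,
         CSF_LV = unname(lv_in), CSF_TFV = unname(tfv_in),
         CSF_CM = 0, CSF_SAS = 0)
  list(M = M, b = b, vap = vap, fu_eff = fu_eff,
       clearances = list(
         bbb_in = unname(bbb_in), bbb_out = unname(bbb_out),
         bcsfb_lv_in = unname(lv_in), bcsfb_lv_out = unname(lv_out),
         bcsfb_tfv_in = unname(tfv_in), bcsfb_tfv_out = unname(tfv_out),
         ecf_icf_fwd = unname(ei_f), ecf_icf_back = unname(ei_b),
         icf_lyso_fwd = unname(il_f), icf_lyso_back = unname(il_b),
         csf_chain_flow = c(LV = flow_lv, TFV = flow_tfv, CM = flow_cm,
                            SAS = flow_sas)))
}

# steady-state unbound concentration ratios (compartment : plasma) under a
# constant unit unbound plasma infusion
.ss_ratios <- function(sys, cp = 1) {
  amounts <- solve(sys$M, -sys$b * cp)
  stats::setNames(amounts / sys$vap / cp, .cns_compartments)
}

#' Calibrate a barrier asymmetry factor against a Kpuu target
#'
#' Root-finds the directional asymmetry factor at one barrier so that, under
#' a constant unit unbound plasma infusion, the steady-state unbound
#' concentration ratio of the barrier's calibration compartment
#' (brain ECF for the BBB, CSF_LV and CSF_TFV for the two BCSFB faces)
#' equals the Kpuu target within 1e-3 relative. The asymmetry factor is
#' reported as a magnitude >= 1 with a direction.
#'
#' @param p A `cns_physiology` set.
#' @param d A `cns_drug` record.
#' @param barrier `"BBB"`, `"BCSFB_LV"` or `"BCSFB_TFV"`.
#' @param kpuu_target Target unbound partition coefficient (> 0).
#' @param theta_fixed Named list of already-calibrated net asymmetry
#'   parameters for the other barriers (upstream barriers must be calibrated
#'   first: BBB, then BCSFB_LV, then BCSFB_TFV).
#' @param tp Transport parameter map.
#' @param bulk_route ECF bulk-flow destination compartment.
#' @return A list: `af_in`, `af_ef` (magnitudes >= 1), `theta` (net
#'   parameter), `achieved` (steady-state ratio at the calibrated theta).
#' @export
calibrate_af <- function(p, d, barrier = c("BBB", "BCSFB_LV", "BCSFB_TFV"),
                         kpuu_target, theta_fixed = list(),
                         tp = transport_params(), bulk_route = "CSF_LV") {
  barrier <- match.arg(barrier)
  stopifnot(kpuu_target > 0)
  cl <- passive_clearances(p, d, tp)
  comp <- c(BBB = "brain_ECF", BCSFB_LV = "CSF_LV", BCSFB_TFV = "CSF_TFV")[barrier]
  th <- utils::modifyList(list(theta_bbb = 1, theta_lv = 1, theta_tfv = 1),
                          theta_fixed)
  slot <- c(BBB = "theta_bbb", BCSFB_LV = "theta_lv",
            BCSFB_TFV = "theta_tfv")[barrier]
  ratio_at <- function(log_theta) {
    th[[slot]] <- 10^log_theta
    sys <- do.call(.assemble_system,
                   c(list(p = p, d = d, cl = cl, bulk_route = bulk_route), th))
    unname(.ss_ratios(sys)[comp])
  }
  lo <- -6; hi <- 6
  f <- function(lt) log(ratio_at(lt) / kpuu_target)
  flo <- f(lo); fhi <- f(hi)
  if (is.nan(flo) || is.nan(fhi) || flo * fhi > 0) {
    rlang::abort(
      sprintf(
        "Kpuu target %.3g at %s unreachable with asymmetry factors <= 1e6; achievable ratio range [%.3g, %.3g]",
        kpuu_target, barrier, exp(flo) * kpuu_target, exp(fhi) * kpuu_target
      ),
      class = "cnspbpk_calibration_error"
    )
  }
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  theta <- 10^root
  list(af_in = max(theta, 1), af_ef = max(1 / theta, 1), theta = theta,
       achieved = ratio_at(root))
}

#' Build the CNS PBPK model for a drug and a population physiology
#'
#' Assembles the linear 9-compartment mass-balance system (8 CNS states
#' driven by the plasma forcing function): BBB and BCSFB paracellular and
#' neutral-species transcellular transport with calibrated asymmetry
#' factors, ECF-ICF and ICF-lysosome membrane exchange with pH partitioning,
#' ECF bulk flow, the CSF production chain (lateral ventricles -> third/
#' fourth ventricles -> cisterna magna -> subarachnoid space -> absorption
#' sink), and phospholipid binding as an instantaneous equilibrium scaling
#' the apparent tissue volumes.
#'
#' Asymmetry factors are calibrated against `kpuu_bbb` (brain ECF),
#' `kpuu_lv` (CSF_LV) and `kpuu_lumbar` (applied at the third/fourth-
#' ventricle BCSFB face, whose ratio the subarachnoid compartment inherits
#' through the CSF chain). Rat-derived BBB targets are first calibrated in
#' place, then translated to human by the transporter expression ratios
#' ([scale_asymmetry_species()]).
#'
#' @param p A validated `cns_physiology` set.
#' @param d A `cns_drug` record.
#' @param af Optional precomputed asymmetry tibble (as returned in
#'   `model$af`) to skip calibration (used by the sensitivity analysis).
#' @param tp Transport parameter map.
#' @param bulk_route ECF bulk-flow destination: `"CSF_LV"` (default),
#'   `"CSF_CM"` or `"CSF_SAS"`. The default keeps the bulk inflow upstream
#'   of both calibrated BCSFB faces so calibrated ratios propagate down the
#'   CSF chain unchanged.
#' @param csf_sink Keep the SAS absorption sink (disable only for mass-
#'   balance checks).
#' @return A `cns_model` object: system matrix `M`, input vector `b`,
#'   apparent volumes `vap`, asymmetry table `af`, clearance table, and the
#'   inputs.
#' @examples
#' mod <- build_model(build_population("AD", age = 70), load_drug("memantine"))
#' mod$af
#' @export
build_model <- function(p, d, af = NULL, tp = transport_params(),
                        bulk_route = c("CSF_LV", "CSF_CM", "CSF_SAS"),
                        csf_sink = TRUE) {
  bulk_route <- match.arg(bulk_route)
  report <- validate_physiology(p, consistency = FALSE)
  if (nrow(report) > 0) {
    rlang::abort(paste0("Physiology invalid for model build: ",
                        paste(report$field, collapse = ", ")),
                 class = "cnspbpk_validation_error")
  }
  cl <- passive_clearances(p, d, tp)
  if (is.null(af)) {
    # BBB: calibrate, with rat -> human translation when applicable
    bbb <- calibrate_af(p, d, "BBB", d$kpuu_bbb, tp = tp,
                        bulk_route = bulk_route)
    theta_bbb <- bbb$theta
    if (identical(d$kpuu_bbb_species, "rat") && length(d$species_scaling) > 0) {
      applicable <- d$species_scaling[names(d$species_scaling) %in%
                                        d$transporter_substrate]
      if (length(applicable) > 0) {
        dir <- if (theta_bbb >= 1) "influx" else "efflux"
        mag <- max(theta_bbb, 1 / theta_bbb)
        scaled <- scale_asymmetry_species(mag, dir, applicable)
        theta_bbb <- if (scaled$direction == "influx") scaled$af else 1 / scaled$af
      }
    }
    lv <- calibrate_af(p, d, "BCSFB_LV", d$kpuu_lv,
                       theta_fixed = list(theta_bbb = theta_bbb),
                       tp = tp, bulk_route = bulk_route)
    tfv <- calibrate_af(p, d, "BCSFB_TFV", d$kpuu_lumbar,
                        theta_fixed = list(theta_bbb = theta_bbb,
                                           theta_lv = lv$theta),
                        tp = tp, bulk_route = bulk_route)
    af <- tibble::tibble(
      barrier = c("BBB", "BCSFB_LV", "BCSFB_TFV"),
      af_in = c(max(theta_bbb, 1), lv$af_in, tfv$af_in),
      af_ef = c(max(1 / theta_bbb, 1), lv$af_ef, tfv$af_ef),
      theta = c(theta_bbb, lv$theta, tfv$theta),
      kpuu_target = c(d$kpuu_bbb, d$kpuu_lv, d$kpuu_lumbar)
    )
  }
  theta <- stats::setNames(af$theta, af$barrier)
  sys <- .assemble_system(p, d, cl,
                          theta_bbb = theta[["BBB"]],
                          theta_lv = theta[["BCSFB_LV"]],
                          theta_tfv = theta[["BCSFB_TFV"]],
                          bulk_route = bulk_route, csf_sink = csf_sink)
  structure(
    list(M = sys$M, b = sys$b, vap = sys$vap, fu_eff = sys$fu_eff,
         af = af, clearances = sys$clearances, passive = cl,
         phys = p, drug = d, tp = tp, bulk_route = bulk_route,
         csf_sink = csf_sink, compartments = .cns_compartments),
    class = "cns_model"
  )
}

#' @export
print.cns_model <- function(x, ...) {
  cat(sprintf("<cns_model> %s in %s (age %s): 8 CNS states + plasma forcing\n",
              x$drug$name, x$phys$population, x$phys$age))
  print(x$af)
  invisible(x)
}

#' Steady-state unbound concentration ratios under constant plasma infusion
#'
#' @param model A `cns_model`.
#' @param cp Constant unbound plasma concentration (ng/mL).
#' @return Named vector of compartment:plasma unbound concentration ratios.
#' @export
steady_state_ratios <- function(model, cp = 1) {
  .ss_ratios(model, cp = cp)
}

#' Integrate the CNS model over a time grid
#'
#' Stiff-capable integration (`deSolve::lsoda`, relative tolerance 1e-8) of
#' the linear CNS system driven by an unbound plasma concentration forcing
#' function.
#'
#' @param model A `cns_model`.
#' @param plasma The forcing: a function of time returning ng/mL, a
#'   `cns_profile` tibble containing a `"plasma"` compartment (interpolated
#'   linearly), or a single number (constant infusion).
#' @param grid Strictly increasing time grid, minutes.
#' @param y0 Initial amounts (ng) per compartment (default all zero).
#' @return A `cns_profile` tibble (long format: `time`, `compartment`,
#'   `conc`) containing the 8 CNS compartments plus the plasma forcing;
#'   the final state vector is attached as attribute `y_end`.
#' @export
simulate_cns <- function(model, plasma, grid, y0 = NULL) {
  stopifnot(length(grid) > 1, all(diff(grid) > 0))
  cp_fun <- .as_forcing(plasma)
  y0 <- y0 %||% stats::setNames(numeric(8), .cns_compartments)
  M <- model$M; b <- model$b
  rhs <- function(t, y, parms) list(M %*% y + b * cp_fun(t))
  scale <- max(abs(cp_fun(grid)), 1e-12) * max(model$vap)
  sol <- try(deSolve::lsoda(y0, grid, rhs, parms = NULL,
                            rtol = 1e-8, atol = 1e-12 * scale), silent = TRUE)
  if (inherits(sol, "try-error") || nrow(sol) < length(grid)) {
    ev <- eigen(M, only.values = TRUE)$values
    rlang::abort(
      sprintf("CNS integrator failure (stiffness ratio %.3g; worst compartment %s)",
              max(abs(Re(ev))) / max(min(abs(Re(ev))), 1e-300),
              model$compartments[which.max(abs(diag(M)))]),
      class = "cnspbpk_integration_error"
    )
  }
  conc <- sweep(sol[, model$compartments, drop = FALSE], 2, model$vap, "/")
  out <- tibble::tibble(
    time = rep(sol[, "time"], times = ncol(conc) + 1),
    compartment = rep(c(model$compartments, "plasma"), each = nrow(sol)),
    conc = c(pmax(conc, 0), pmax(cp_fun(sol[, "time"]), 0))
  )
  prof <- new_profile(out, drug = model$drug$name,
                      population = model$phys$population, regimen = NULL)
  attr(prof, "y_end") <- sol[nrow(sol), model$compartments]
  prof
}

.as_forcing <- function(plasma) {
  if (is.function(plasma)) return(plasma)
  if (is.numeric(plasma) && length(plasma) == 1) {
    force(plasma)
    return(function(t) rep(plasma, length(t)))
  }
  if (inherits(plasma, "data.frame")) {
    pl <- plasma[plasma$compartment == "plasma", ]
    if (nrow(pl) == 0) {
      rlang::abort("Forcing profile contains no 'plasma' compartment",
                   class = "cnspbpk_domain_error")
    }
    return(stats::approxfun(pl$time, pl$conc, rule = 2))
  }
  rlang::abort("Unsupported plasma forcing type", class = "cnspbpk_domain_error")
}

# ---- concentration profile container ---------------------------------------

#' Construct a concentration-profile tibble
#'
#' @param data Tibble with columns `time` (min, strictly increasing within
#'   each compartment), `compartment`, `conc` (ng/mL, unbound).
#' @param drug,population,regimen Metadata attached as attributes.
#' @return A `cns_profile` tibble.
#' @keywords internal
#' @export
new_profile <- function(data, drug = NA_character_,
                        population = NA_character_, regimen = NULL) {
  stopifnot(all(c("time", "compartment", "conc") %in% names(data)))
  structure(data,
            class = c("cns_profile", class(tibble::as_tibble(data))),
            drug = drug, population = population, regimen = regimen)
}

#' Interpolate a profile at given times
#' @param profile A `cns_profile`.
#' @param compartment Compartment label.
#' @param times Times (min) within the profile span.
#' @return Numeric concentrations.
#' @export
profile_interp <- function(profile, compartment, times) {
  sub <- profile[profile$compartment == compartment, ]
  if (nrow(sub) == 0) {
    rlang::abort(paste0("No compartment '", compartment, "' in profile"),
                 class = "cnspbpk_domain_error")
  }
  stats::approx(sub$time, sub$conc, xout = times, rule = 2)$y
}
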