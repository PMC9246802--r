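#' Specification for synthetic drug and observation generation
#'
#' Ranges for physically plausible random drug records and the observation
#' noise model used to emulate sparse clinical CSF sampling. Noise is
#' multiplicative log-normal (concentrations are positive and assay error is
#' characterised by a coefficient of variation), median-unbiased on the
#' ratio scale.
#'
#' @param logp_range,mw_range,pka_base_range,pka_acid_range Uniform sampling
#'   ranges for lipophilicity, molecular weight (g/mol) and ionisation
#'   constants.
#' @param p_base,p_acid Probability that the random drug carries a basic /
#'   acidic group.
#' @param fu_range Log-uniform range for the unbound fractions (plasma and
#'   brain).
#' @param kpuu_range Log-uniform range for the Kpuu calibration targets.
#' @param ic50_range Log-uniform range for the unbound IC50 (ng/mL).
#' @param cv Observation noise coefficient of variation (default 0.2).
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(logp_range = c(-1, 5), mw_range = c(150, 600),
                           pka_base_range = c(5, 12),
                           pka_acid_range = c(3, 11),
                           p_base = 0.5, p_acid = 0.25,
                           fu_range = c(0.01, 1),
                           kpuu_range = c(0.1, 5),
                           ic50_range = c(1, 1000),
                           cv = 0.2) {
  structure(as.list(environment()), class = "synthetic_spec")
}

.runif_log <- function(n, range) exp(stats::runif(n, log(range[1]), log(range[2])))

#' Generate a random, physically consistent drug record
#'
#' Draws a `cns_drug` record from the ranges in a [synthetic_spec()]: at
#' most one acidic and one basic group, log-uniform unbound fractions and
#' Kpuu targets. Identical seeds give identical records.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed.
#' @return A validated `cns_drug` record (no plasma model attached).
#' @export
generate_drug <- function(spec = synthetic_spec(), seed = 1) {
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  has_base <- stats::runif(1) < spec$p_base
  has_acid <- stats::runif(1) < spec$p_acid
  cfg <- list(
    name = paste0("synthetic-", seed),
    mw = stats::runif(1, spec$mw_range[1], spec$mw_range[2]),
    logp = stats::runif(1, spec$logp_range[1], spec$logp_range[2]),
    pka_base = if (has_base) stats::runif(1, spec$pka_base_range[1],
                                          spec$pka_base_range[2]) else NA_real_,
    pka_acid = if (has_acid) stats::runif(1, spec$pka_acid_range[1],
                                          spec$pka_acid_range[2]) else NA_real_,
    fu_p = .runif_log(1, spec$fu_range),
    fu_b = .runif_log(1, spec$fu_range),
    kpuu_bbb = .runif_log(1, spec$kpuu_range),
    kpuu_lv = .runif_log(1, spec$kpuu_range),
    kpuu_lumbar = .runif_log(1, spec$kpuu_range),
    ic50_unbound = .runif_log(1, spec$ic50_range),
    kpuu_bbb_species = "human"
  )
  new_drug(cfg)
}

#' Sample noisy observations from a simulated profile
#'
#' Interpolates the true profile at the sampling schedule and applies
#' multiplicative log-normal noise with the stated coefficient of
#' variation (median-unbiased: the geometric mean of observed:true ratios
#' converges to 1). The paired truth is retained for recovery tests.
#'
#' @param profile A `cns_profile`.
#' @param schedule Sampling times (min) within the profile span.
#' @param cv Coefficient of variation of the noise (0 = noise-free).
#' @param seed Integer seed.
#' @param compartment Compartment to sample (default `"CSF_SAS"`).
#' @return A tibble: `time`, `compartment`, `truth`, `obs`.
#' @export
generate_observations <- function(profile, schedule, cv = 0.2, seed = 1,
                                  compartment = "CSF_SAS") {
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  truth <- profile_interp(profile, compartment, schedule)
  sdlog <- sqrt(log(1 + cv^2))
  obs <- truth * exp(stats::rnorm(length(schedule), mean = 0, sd = sdlog))
  tibble::tibble(time = schedule, compartment = compartment,
                 truth = truth, obs = obs)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
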