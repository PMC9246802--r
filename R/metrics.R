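#' Run a CNS model to steady state under repeated dosing
#'
#' Integrates the CNS system interval by interval under the periodic
#' steady-state plasma forcing, carrying the state forward, until the
#' interdose AUC of every CNS compartment changes by less than `tol`
#' (default 0.5%) between consecutive intervals and at least five plasma
#' terminal half-lives have been simulated. Chronic runs start from the
#' constant-infusion steady state at the average steady-state plasma level,
#' so the iteration equilibrates the periodic ripple rather than the slow
#' filling of deep depots (lysosomal trapping). Returns the final interval
#' re-indexed to time post-dose. For a finite single-dose regimen
#' (`n_doses = 1`) the first interval is returned, flagged as not at steady
#' state.
#'
#' @param model A `cns_model`.
#' @param plasma_model A [plasma_model()] (defaults to the model drug's
#'   registry plasma model).
#' @param regimen A [dose_regimen()] (defaults to the registry regimen with
#'   chronic dosing).
#' @param n_points Grid points per interval (default 1001).
#' @param tol Relative interdose-AUC convergence tolerance (default 0.005).
#' @param max_intervals Error if not converged within this many intervals.
#' @return A `cns_profile` over one interval (time post-dose), with
#'   attributes `at_steady_state`, `n_intervals`, `auc_tau` (named vector)
#'   and `interval`.
#' @examples
#' \donttest{
#' d <- load_drug("semagacestat")
#' mod <- build_model(build_population("AD", age = 70), d)
#' ss <- run_to_steady_state(mod)
#' attr(ss, "n_intervals")
#' }
#' @export
run_to_steady_state <- function(model, plasma_model = NULL, regimen = NULL,
                                n_points = 1001, tol = 0.005,
                                max_intervals = 200) {
  pm <- plasma_model %||% model$drug$plasma
  rg <- regimen %||% model$drug$regimen
  if (is.null(pm) || is.null(rg)) {
    rlang::abort("plasma model and regimen required (none attached to the drug record)",
                 class = "cnspbpk_domain_error")
  }
  tau <- rg$interval
  grid <- seq(0, tau, length.out = n_points)

  if (is.finite(rg$n_doses) && rg$n_doses <= 1) {
    cp <- plasma_conc_fun(pm, rg)
    prof <- simulate_cns(model, cp, grid)
    attr(prof, "at_steady_state") <- FALSE
    attr(prof, "n_intervals") <- 1L
    attr(prof, "auc_tau") <- .profile_aucs(prof)
    attr(prof, "interval") <- tau
    attr(prof, "regimen") <- rg
    return(prof)
  }

  cp <- plasma_conc_fun(pm, dose_regimen(rg$dose, tau, n_doses = Inf, rg$route))
  modes <- .plasma_modes(pm, rg$dose)
  lam_min <- if (isTRUE(modes$degenerate)) modes$k else min(modes$lambda)
  t_half <- log(2) / lam_min
  min_intervals <- max(2, ceiling(5 * t_half / tau))

  # warm start at the constant-infusion steady state matching the average
  # steady-state plasma level (exact for the interval averages of this
  # linear system); the interval iteration then only has to equilibrate the
  # periodic ripple, which keeps slowly-filling depots (lysosomal trapping)
  # from stalling the interdose-AUC criterion far from the periodic orbit
  cavg_ss <- pm$f_rel * rg$dose * 1e6 / pm$cl_cen / tau
  y0 <- stats::setNames(
    if (rg$dose > 0) drop(solve(model$M, -model$b * cavg_ss)) else numeric(8),
    model$compartments
  )
  auc_prev <- NULL
  prof <- NULL
  converged <- FALSE
  for (k in seq_len(max_intervals)) {
    prof <- simulate_cns(model, cp, grid, y0 = y0)
    y0 <- attr(prof, "y_end")
    auc <- .profile_aucs(prof)
    if (!is.null(auc_prev) && k >= min_intervals) {
      rel <- abs(auc - auc_prev) / pmax(auc, 1e-300)
      nz <- auc > 1e-300
      if (!any(nz) || max(rel[nz]) < tol) {
        converged <- TRUE
        break
      }
    }
    auc_prev <- auc
  }
  if (!converged && rg$dose > 0) {
    rlang::abort(sprintf("No steady state within %d intervals", max_intervals),
                 class = "cnspbpk_convergence_error")
  }
  attr(prof, "at_steady_state") <- TRUE
  attr(prof, "n_intervals") <- k
  attr(prof, "auc_tau") <- .profile_aucs(prof)
  attr(prof, "interval") <- tau
  attr(prof, "regimen") <- rg
  prof
}

.trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

.profile_aucs <- function(prof) {
  comps <- unique(prof$compartment)
  vapply(comps, function(cc) {
    sub <- prof[prof$compartment == cc, ]
    .trapz(sub$time, sub$conc)
  }, numeric(1))
}

# parabolic refinement of a grid extremum at index i
.refine_extremum <- function(t, y, i) {
  if (i <= 1 || i >= length(t)) return(c(t = t[i], y = y[i]))
  t3 <- t[(i - 1):(i + 1)]; y3 <- y[(i - 1):(i + 1)]
  co <- tryCatch(solve(cbind(1, t3, t3^2), y3), error = function(e) NULL)
  if (is.null(co) || !is.finite(co[3]) || co[3] == 0) {
    return(c(t = t[i], y = y[i]))
  }
  tv <- -co[2] / (2 * co[3])
  if (!is.finite(tv) || tv < t3[1] || tv > t3[3]) return(c(t = t[i], y = y[i]))
  c(t = unname(tv), y = unname(co[1] + co[2] * tv + co[3] * tv^2))
}

#' Steady-state PK summary metrics per compartment
#'
#' Computes Cmax, Cmin, Tmax (grid scan with local parabolic refinement),
#' AUC over the interval (trapezoid), fluctuation (Cmax:Cmin), average
#' concentration (AUC/tau), and the terminal half-life from a log-linear
#' least-squares fit over the last 30% of the interval past Tmax. A
#' non-positive tail yields an undefined (NA) half-life, not an error.
#'
#' @param profile A single-interval `cns_profile` (>= 50 grid points per
#'   compartment).
#' @param compartments Compartments to summarise (default: all present).
#' @return A `cns_pk_metrics` tibble: `compartment`, `cmax`, `cmin`, `tmax`,
#'   `auc_tau`, `cavg`, `half_life`, `fluctuation`.
#' @export
compute_metrics <- function(profile, compartments = NULL) {
  compartments <- compartments %||% unique(profile$compartment)
  rows <- purrr::map(compartments, function(cc) {
    sub <- profile[profile$compartment == cc, ]
    if (nrow(sub) < 50) {
      rlang::abort("compute_metrics needs >= 50 grid points per compartment",
                   class = "cnspbpk_domain_error")
    }
    t <- sub$time; y <- sub$conc
    tau <- max(t) - min(t)
    imax <- which.max(y); imin <- which.min(y)
    pk <- .refine_extremum(t, y, imax)
    tr <- .refine_extremum(t, y, imin)
    cmax <- max(pk["y"], max(y)); cmin <- min(tr["y"], min(y))
    auc <- .trapz(t, y)
    # terminal log-linear tail: last 30% of the interval, past Tmax
    tail_start <- max(min(t) + 0.7 * tau, pk["t"])
    tl <- t >= tail_start
    half_life <- NA_real_
    if (sum(tl) >= 3 && all(y[tl] > 0) && stats::sd(y[tl]) > 0) {
      slope <- stats::coef(stats::lm(log(y[tl]) ~ t[tl]))[2]
      if (is.finite(slope) && slope < 0) half_life <- log(2) / -slope
    }
    tibble::tibble(
      compartment = cc,
      cmax = unname(cmax), cmin = unname(cmin), tmax = unname(pk["t"] - min(t)),
      auc_tau = auc, cavg = auc / tau,
      half_life = unname(half_life),
      fluctuation = if (cmin > 0) unname(cmax / cmin) else Inf
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cns_pk_metrics", class(out))
  attr(out, "drug") <- attr(profile, "drug")
  attr(out, "population") <- attr(profile, "population")
  out
}

#' Target-engagement summary against an unbound IC50
#'
#' Finds IC50 crossing times by linear interpolation between grid points,
#' the fraction of the interval spent at or above the IC50, and the
#' drug-free onset: the first downward crossing with no later upward
#' crossing (NA if the profile never ends below the IC50; 0 if it is always
#' below).
#'
#' @param profile A single-interval `cns_profile`.
#' @param ic50_unbound Unbound IC50, ng/mL (> 0).
#' @param compartments Compartments to analyse (default: all present).
#' @return A `cns_engagement` tibble: `compartment`, `fraction_above`,
#'   `n_crossings`, `drug_free_onset` (min post-dose), `always_above`,
#'   `always_below`.
#' @export
engagement <- function(profile, ic50_unbound, compartments = NULL) {
  stopifnot(ic50_unbound > 0)
  compartments <- compartments %||% unique(profile$compartment)
  rows <- purrr::map(compartments, function(cc) {
    sub <- profile[profile$compartment == cc, ]
    t <- sub$time - min(sub$time); y <- sub$conc
    tau <- max(t)
    above <- y >= ic50_unbound
    crossings <- tibble::tibble(time = numeric(0), direction = character(0))
    time_above <- 0
    for (i in seq_len(length(t) - 1)) {
      y1 <- y[i]; y2 <- y[i + 1]; dt <- t[i + 1] - t[i]
      a1 <- above[i]; a2 <- above[i + 1]
      if (a1 && a2) {
        time_above <- time_above + dt
      } else if (a1 != a2) {
        tc <- t[i] + dt * (ic50_unbound - y1) / (y2 - y1)
        crossings <- dplyr::bind_rows(crossings, tibble::tibble(
          time = tc, direction = if (a1) "down" else "up"))
        time_above <- time_above + if (a1) tc - t[i] else t[i + 1] - tc
      }
    }
    frac <- min(max(time_above / tau, 0), 1)
    onset <- NA_real_
    if (all(!above)) {
      onset <- 0
    } else if (nrow(crossings) > 0) {
      downs <- crossings$time[crossings$direction == "down"]
      ups <- crossings$time[crossings$direction == "up"]
      final_downs <- downs[vapply(downs, function(td) !any(ups > td), TRUE)]
      if (length(final_downs) > 0) onset <- min(final_downs)
    }
    tibble::tibble(
      compartment = cc, fraction_above = frac,
      n_crossings = nrow(crossings), drug_free_onset = onset,
      always_above = all(above), always_below = all(!above)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cns_engagement", class(out))
  attr(out, "ic50_unbound") <- ic50_unbound
  out
}
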