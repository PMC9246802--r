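test_that("metrics on closed-form profiles match analytic values", {
  # constant profile: no fluctuation, peak at the start
  t <- seq(0, 720, length.out = 200)
  const <- new_profile(tibble::tibble(time = t, compartment = "brain_ECF",
                                      conc = 7))
  m <- compute_metrics(const)
  expect_equal(m$fluctuation, 1)
  expect_equal(m$tmax, 0)
  expect_equal(m$auc_tau, 7 * 720)

  # mono-exponential decay: fluctuation e^(k tau), half-life ln2/k
  k <- 0.004
  prof <- exp_decay_profile(k, c0 = 100, tau = 720, n = 1441)
  m2 <- compute_metrics(prof)
  expect_equal(m2$fluctuation, exp(k * 720), tolerance = 0.005)
  expect_equal(m2$half_life, log(2) / k, tolerance = 0.005)
  expect_equal(m2$cmax, 100, tolerance = 1e-6)

  # triangular profile: parabolic refinement recovers an off-grid peak
  tt <- seq(0, 100, length.out = 101)
  tri <- new_profile(tibble::tibble(
    time = tt, compartment = "x",
    conc = 10 - 0.02 * (tt - 40.5)^2
  ))
  m3 <- compute_metrics(tri)
  expect_equal(m3$tmax, 40.5, tolerance = 1e-6)
  expect_equal(m3$cmax, 10, tolerance = 1e-6)

  # a non-positive tail yields an undefined half-life, not an error
  dip <- new_profile(tibble::tibble(time = t, compartment = "x",
                                    conc = pmax(100 - 0.2 * t, 0)))
  expect_true(is.na(compute_metrics(dip)$half_life))
})

test_that("metrics are stable under grid refinement", {
  k <- 0.003
  coarse <- compute_metrics(exp_decay_profile(k, tau = 720, n = 1001))
  fine <- compute_metrics(exp_decay_profile(k, tau = 720, n = 4001))
  for (col in c("cmax", "cmin", "auc_tau", "half_life", "fluctuation")) {
    expect_equal(coarse[[col]], fine[[col]], tolerance = 1e-3, info = col)
  }
})

test_that("engagement crossings and fractions follow the closed form", {
  t <- seq(0, 720, length.out = 1441)
  hi <- new_profile(tibble::tibble(time = t, compartment = "x", conc = 50))
  e_hi <- engagement(hi, 10)
  expect_equal(e_hi$fraction_above, 1)
  expect_equal(e_hi$n_crossings, 0)
  expect_true(e_hi$always_above)
  expect_true(is.na(e_hi$drug_free_onset))

  lo <- new_profile(tibble::tibble(time = t, compartment = "x", conc = 1))
  e_lo <- engagement(lo, 10)
  expect_equal(e_lo$fraction_above, 0)
  expect_true(e_lo$always_below)
  expect_equal(e_lo$drug_free_onset, 0)

  # C0 e^(-kt) with C0/ic50 = e^(k tau / 2): crossing at tau/2, fraction 1/2
  k <- 0.005
  tau <- 720
  ic50 <- 20
  c0 <- ic50 * exp(k * tau / 2)
  prof <- exp_decay_profile(k, c0 = c0, tau = tau, n = 1441)
  e <- engagement(prof, ic50)
  expect_equal(e$fraction_above, 0.5, tolerance = 1e-3)
  expect_equal(e$drug_free_onset, tau / 2, tolerance = 1)
  expect_equal(e$n_crossings, 1)
})

test_that("fraction above IC50 is monotone non-increasing in the IC50", {
  prof <- exp_decay_profile(0.004, c0 = 500, tau = 720, n = 721)
  ic50s <- c(0.5, 2, 10, 50, 200, 1000)
  fr <- vapply(ic50s, function(x) engagement(prof, x)$fraction_above, numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("steady-state interdose AUC matches the analytic dose/CL identity", {
  d <- load_drug("semagacestat")
  mod <- build_model(build_population("AD", age = 70), d)
  ss <- run_to_steady_state(mod)
  expect_true(attr(ss, "at_steady_state"))
  auc_pl <- attr(ss, "auc_tau")[["plasma"]]
  expect_equal(auc_pl, 140e6 / 846, tolerance = 0.005)
  # brain interval-average equals the calibrated Kpuu times the plasma average
  m <- compute_metrics(ss, c("plasma", "brain_ECF"))
  expect_equal(m$cavg[m$compartment == "brain_ECF"] /
                 m$cavg[m$compartment == "plasma"], 0.55, tolerance = 0.01)
})

test_that("a single-dose regimen returns the first interval, not steady state", {
  d <- load_drug("semagacestat")
  mod <- build_model(build_population("CHY"), d)
  prof <- run_to_steady_state(mod, regimen = dose_regimen(140, 1440, n_doses = 1))
  expect_false(attr(prof, "at_steady_state"))
  expect_equal(attr(prof, "n_intervals"), 1L)
  expect_equal(max(prof$time), 1440)
})
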