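chy <- load_physiology()

test_that("passive clearances scale as designed", {
  d <- toy_neutral_drug(logp = 2, mw = 80)
  d8 <- toy_neutral_drug(logp = 2, mw = 640)
  cl1 <- passive_clearances(chy, d)
  cl8 <- passive_clearances(chy, d8)
  # cube-root aqueous diffusion scaling: 8x the mass halves P_para
  expect_equal(cl8$p_para / cl1$p_para, 0.5, tolerance = 1e-12)
  # paracellular multiplier acts exactly linearly
  p44 <- chy
  p44$f_paracellular_bbb <- 4.4
  cl44 <- passive_clearances(p44, d)
  expect_equal(cl44$cl_para_bbb, 4.4 * cl1$cl_para_bbb, tolerance = 1e-12)
  expect_equal(cl44$cl_trans_bbb, cl1$cl_trans_bbb)
  # transcellular permeability increases monotonically with lipophilicity
  lo <- passive_clearances(chy, toy_neutral_drug(logp = -2, mw = 300))
  hi <- passive_clearances(chy, toy_neutral_drug(logp = 3, mw = 300))
  expect_lt(lo$cl_trans_bbb, hi$cl_trans_bbb)
})

test_that("asymmetry calibration recovers a known factor (round-trip oracle)", {
  d <- toy_neutral_drug(kpuu = 1)
  af <- tibble::tibble(
    barrier = c("BBB", "BCSFB_LV", "BCSFB_TFV"),
    af_in = c(3, 1, 1), af_ef = c(1, 1, 1), theta = c(3, 1, 1),
    kpuu_target = NA_real_
  )
  forced <- build_model(chy, d, af = af)
  achieved <- steady_state_ratios(forced)[["brain_ECF"]]
  cal <- calibrate_af(chy, d, "BBB", kpuu_target = achieved)
  expect_equal(cal$af_in, 3, tolerance = 1e-3)
  expect_equal(cal$af_ef, 1)
})

test_that("bulk-flow washout forces the influx factor above the Kpuu target", {
  d <- toy_neutral_drug(kpuu = 2)
  cal <- calibrate_af(chy, d, "BBB", kpuu_target = 2)
  expect_gt(cal$af_in, 2)
  expect_equal(cal$achieved, 2, tolerance = 1e-3)
  # without bulk flow and with symmetric passive transport, a unit target
  # needs no asymmetry
  p0 <- chy
  p0$q_ecf_bulk <- 1e-12
  cal0 <- calibrate_af(p0, toy_neutral_drug(kpuu = 1), "BBB", kpuu_target = 1)
  expect_equal(cal0$af_in, 1, tolerance = 1e-6)
  expect_equal(cal0$af_ef, 1, tolerance = 1e-6)
})

test_that("unreachable Kpuu targets raise a calibration error with the range", {
  d <- toy_neutral_drug()
  expect_error(calibrate_af(chy, d, "BBB", kpuu_target = 1e9),
               class = "cnspbpk_calibration_error")
  expect_error(calibrate_af(chy, d, "BBB", kpuu_target = 1e9), "achievable")
})

test_that("built models encode net transport direction from the Kpuu targets", {
  ad <- build_population("AD", age = 70)
  mem <- build_model(ad, load_drug("memantine"))
  bbb <- mem$af[mem$af$barrier == "BBB", ]
  expect_gt(bbb$af_in, 1) # Kpuu,BBB = 2 needs net influx
  expect_equal(bbb$af_ef, 1)
  sem <- build_model(ad, load_drug("semagacestat"))
  expect_gt(sem$af$af_ef[sem$af$barrier == "BCSFB_LV"], 1) # Kpuu 0.55 net efflux
  # calibrated steady-state ratios hit their targets
  r <- steady_state_ratios(mem)
  expect_equal(r[["brain_ECF"]], 2, tolerance = 1e-3)
  expect_equal(r[["CSF_LV"]], 0.89, tolerance = 1e-3)
  expect_equal(r[["CSF_TFV"]], 0.89, tolerance = 1e-3)
})

test_that("the subarachnoid compartment inherits the lumbar Kpuu through the CSF chain", {
  ad <- build_population("AD", age = 70)
  for (nm in c("donepezil", "galantamine", "memantine", "rivastigmine",
               "semagacestat")) {
    mod <- build_model(ad, load_drug(nm))
    r <- steady_state_ratios(mod)
    expect_equal(r[["CSF_SAS"]], load_drug(nm)$kpuu_lumbar, tolerance = 0.1,
                 info = nm)
  }
})

test_that("zero plasma input stays identically zero", {
  mod <- build_model(chy, toy_neutral_drug())
  prof <- simulate_cns(mod, 0, grid = seq(0, 500, by = 5))
  expect_true(all(prof$conc == 0))
})

test_that("constant infusion converges to the calibrated Kpuu ratio", {
  mod <- build_model(chy, load_drug("semagacestat"))
  prof <- simulate_cns(mod, 10, grid = seq(0, 30 * 1440, length.out = 200))
  ecf <- prof[prof$compartment == "brain_ECF", ]
  expect_equal(tail(ecf$conc, 1) / 10, 0.55, tolerance = 0.01)
})

test_that("mass balance closes: every outflow is an inflow elsewhere, to plasma, or the sink", {
  mod <- build_model(chy, toy_base_drug(), csf_sink = FALSE)
  # per-compartment elimination (mL/min per unit concentration): only the
  # microvascular blood and the two BCSFB faces exchange back to plasma once
  # the CSF absorption sink is disabled
  loss <- -colSums(mod$M) * mod$vap
  expected <- c(
    brain_microvascular = chy$q_cbf_total,
    brain_ECF = 0, brain_ICF = 0, lysosome = 0,
    CSF_LV = mod$clearances$bcsfb_lv_out,
    CSF_TFV = mod$clearances$bcsfb_tfv_out,
    CSF_CM = 0, CSF_SAS = 0
  )
  expect_equal(loss, expected, tolerance = 1e-10)

  # close the plasma boundary too and check conservation under integration
  closed <- mod
  diag(closed$M) <- diag(closed$M) + loss / closed$vap
  expect_lt(max(abs(colSums(closed$M))) * max(closed$vap), 1e-10)
  y0 <- stats::setNames(c(5, 4, 3, 2, 1, 1, 1, 1) * closed$vap,
                        names(closed$vap))
  prof <- simulate_cns(closed, 0, grid = seq(0, 5000, by = 25), y0 = y0)
  wide <- tidyr::pivot_wider(prof[prof$compartment != "plasma", ],
                             names_from = "compartment", values_from = "conc")
  total <- as.matrix(wide[, names(closed$vap)]) %*% closed$vap
  expect_lt(max(abs(total - total[1])) / total[1], 1e-6)
})

test_that("the CNS response is linear in the plasma forcing", {
  mod <- build_model(chy, load_drug("galantamine"))
  f <- plasma_conc_fun(load_drug("galantamine")$plasma,
                       dose_regimen(10, 720, n_doses = 2))
  grid <- seq(0, 1440, length.out = 200)
  base <- simulate_cns(mod, f, grid)
  for (k in c(2, 10)) {
    scaled <- simulate_cns(mod, function(t) k * f(t), grid)
    expect_equal(scaled$conc, k * base$conc, tolerance = 1e-6, info = k)
  }
})

test_that("compartment pH only matters for ionisable drugs", {
  d <- toy_neutral_drug(kpuu = 0.8)
  base_mod <- build_model(chy, d)
  shifted <- chy
  shifted$ph_ecf <- 6.8
  shifted$ph_icf <- 7.6
  shifted$ph_lyso <- 6.5
  shifted$ph_csf <- 7.0
  mod2 <- build_model(shifted, d)
  grid <- seq(0, 2000, length.out = 150)
  f <- function(t) 5 * exp(-t / 400)
  expect_equal(simulate_cns(mod2, f, grid)$conc,
               simulate_cns(base_mod, f, grid)$conc, tolerance = 1e-9)
})

test_that("lysosomal trapping of bases follows the pH-partition prediction", {
  d <- toy_base_drug(pka_base = 9)
  mod <- build_model(chy, d)
  r <- steady_state_ratios(mod)
  trap <- r[["lysosome"]] / r[["brain_ICF"]]
  predicted <- fraction_neutral(chy$ph_icf, d) / fraction_neutral(chy$ph_lyso, d)
  expect_equal(trap, predicted, tolerance = 0.01)
})
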