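test_that("aging compounds the printed per-year rates (loop oracle)", {
  chy <- load_physiology()
  che <- apply_aging(chy, 70)
  # independent oracle: 10 one-year multiplicative steps
  bv <- chy$brain_volume
  lv <- chy$v_lv
  cm <- chy$v_cm
  sas <- chy$v_sas
  for (i in 1:10) {
    bv <- bv * (1 - 0.00401)
    lv <- lv * 1.0345
    cm <- cm * 1.0109
    sas <- sas * 1.0078
  }
  expect_equal(che$brain_volume, bv, tolerance = 1e-12)
  expect_equal(che$v_lv, lv, tolerance = 1e-12)
  expect_equal(che$v_cm, cm, tolerance = 1e-12)
  expect_equal(che$v_sas, sas, tolerance = 1e-12)
  # ratio sanity against the compounded closed forms
  expect_equal(che$brain_volume / chy$brain_volume, (1 - 0.00401)^10,
               tolerance = 1e-12)
  expect_equal(che$v_lv / chy$v_lv, 1.0345^10, tolerance = 1e-12)
})

test_that("aging at the onset age is the identity on parameter values", {
  chy <- load_physiology()
  at60 <- apply_aging(chy, 60)
  for (nm in c("brain_volume", "f_ecf", "v_lv", "q_ecf_bulk", "sa_bbb",
               "q_cbf_total", "ph_icf")) {
    expect_equal(at60[[nm]], chy[[nm]], info = nm)
  }
  expect_error(apply_aging(chy, -5), class = "cnspbpk_domain_error")
})

test_that("aging preserves normalised CBF and the microvascular:CBF ratio", {
  chy <- load_physiology()
  che <- apply_aging(chy, 78)
  expect_equal(che$q_cbf_norm, chy$q_cbf_norm)
  expect_equal(che$q_cbf_total, che$q_cbf_norm * brain_mass(che) / 100,
               tolerance = 1e-9)
  expect_equal(che$v_microvasc / che$q_cbf_total,
               chy$v_microvasc / chy$q_cbf_total, tolerance = 1e-9)
  expect_equal(che$ph_icf, chy$ph_icf - 0.001 * 18)
  # unchanged by aging
  expect_equal(che$q_csf, chy$q_csf)
  expect_equal(che$ph_ecf, chy$ph_ecf)
  expect_equal(che$f_paracellular_bbb, chy$f_paracellular_bbb)
})

test_that("brain shrinks and CSF spaces expand monotonically with age", {
  chy <- load_physiology()
  ages <- c(62, 66, 71, 77, 85, 95)
  sets <- lapply(ages, function(a) apply_aging(chy, a))
  bv <- vapply(sets, `[[`, numeric(1), "brain_volume")
  expect_true(all(diff(bv) < 0))
  for (nm in c("v_lv", "v_tfv", "v_cm", "v_sas")) {
    vol <- vapply(sets, `[[`, numeric(1), nm)
    expect_true(all(diff(vol) > 0), info = nm)
  }
  for (s in sets) expect_equal(nrow(validate_physiology(s)), 0)
})

test_that("AD fold changes match the literature-derived factors", {
  che <- apply_aging(load_physiology(), 70)
  ad <- apply_ad(che)
  expect_equal(ad$f_ecf, che$f_ecf * 1.4)
  expect_equal(ad$f_icf, 1 - ad$f_ecf)
  expect_equal(ad$f_paracellular_bbb, che$f_paracellular_bbb * 4.4)
  expect_equal(ad$f_paracellular_bcsfb, che$f_paracellular_bcsfb)
  expect_equal(ad$brain_volume, che$brain_volume * 0.95)
  expect_equal(ad$v_lv, che$v_lv * 1.39)
  expect_equal(ad$v_sas, che$v_sas * 1.21)
  expect_equal(ad$q_csf, che$q_csf)
  expect_equal(ad$q_cbf_norm, che$q_cbf_norm * 0.85)
  expect_equal(ad$f_phospholipid, che$f_phospholipid * 0.9)
  expect_equal(ad$ph_csf, che$ph_csf + 0.018)
  expect_equal(nrow(validate_physiology(ad)), 0)
  # reference ECF fraction 0.2 maps to 0.28 / 0.72 when applied unaged
  ad_ref <- suppressWarnings(apply_ad(load_physiology(),
                                      ad_fold_changes(lumbar_csf_ph_shift = 0)))
  expect_equal(ad_ref$f_ecf, 0.28)
  expect_equal(ad_ref$f_icf, 0.72)
})

test_that("all-unity AD fold changes are the identity translation", {
  che <- apply_aging(load_physiology(), 70)
  unity <- ad_fold_changes(
    brain_volume_factor = 1, ecf_fraction_factor = 1, phospholipid_factor = 1,
    ventricle_factor = 1, extraventricular_factor = 1, cbf_norm_factor = 1,
    ecf_bulk_flow_factor = 1, bbb_sa_factor = 1, bbb_paracellular_factor = 1,
    bcsfb_paracellular_factor = 1, lumbar_csf_ph_shift = 0
  )
  ad <- apply_ad(che, unity)
  for (nm in c("brain_volume", "f_ecf", "f_icf", "v_lv", "v_sas",
               "q_ecf_bulk", "sa_bbb", "q_cbf_total", "ph_csf")) {
    expect_equal(ad[[nm]], che[[nm]], info = nm)
  }
})

test_that("AD factors are CHE-relative and refuse to compose", {
  ad <- build_population("AD", age = 70)
  expect_error(apply_ad(ad), class = "cnspbpk_domain_error")
})

test_that("build_population dispatches and guards severity", {
  chy <- load_physiology()
  same <- build_population("CHY", base = chy)
  expect_equal(same$brain_volume, chy$brain_volume)
  ad <- build_population("AD", base = chy, age = 70)
  manual <- apply_ad(apply_aging(chy, 70))
  expect_equal(ad$brain_volume, manual$brain_volume)
  expect_equal(ad$f_ecf, manual$f_ecf)
  expect_error(build_population("AD", severity = "severe"),
               class = "cnspbpk_domain_error")
  expect_error(build_population("AD", severity = "severe"), "severity")
})
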