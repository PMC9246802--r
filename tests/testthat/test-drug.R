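test_that("shipped registry values match the source drug tables", {
  mem <- load_drug("memantine")
  expect_equal(mem$mw, 179.3)
  expect_equal(mem$logp, 3.31)
  expect_equal(mem$pka_base, 10.7)
  expect_equal(mem$kpuu_bbb, 2)
  expect_equal(mem$ic50_unbound, 109)
  expect_equal(mem$regimen$dose, 20)

  sem <- load_drug("semagacestat")
  expect_equal(sem$kpuu_lumbar, 0.55)
  expect_equal(sem$ic50_unbound, 5.4)
  expect_equal(sem$plasma$cl_cen, 846)
  expect_equal(sem$plasma$v_cen, 71700)
  expect_equal(sem$regimen$dose, 140)

  gal <- load_drug("galantamine")
  expect_equal(gal$plasma$n_compartments, 2L)
  expect_equal(gal$plasma$q_cen_per1, 510)
  expect_equal(gal$plasma$v_per1, 59000)

  don <- load_drug("donepezil")
  expect_equal(don$plasma$n_compartments, 1L) # Q and V_per1 printed as zero
  expect_equal(don$species_scaling, c(pgp = 0.22, bcrp = 1.1))

  riv <- load_drug("rivastigmine")
  expect_equal(riv$ic50_unbound, 857.2)
  expect_equal(riv$ic50_secondary, 9.3) # butyrylcholinesterase
  expect_equal(riv$plasma$f_rel, 1.4)

  expect_error(load_drug("aspirin"), class = "cnspbpk_lookup_error")
  expect_error(load_drug("aspirin"), "registry")
})

test_that("neutral-fraction arithmetic follows Henderson-Hasselbalch", {
  neutral <- toy_neutral_drug()
  expect_equal(fraction_neutral(c(1, 7.4, 13), neutral), c(1, 1, 1))
  mem <- load_drug("memantine")
  # independent arithmetic: 1 / (1 + 10^(10.7 - 7.4))
  expect_equal(fraction_neutral(7.4, mem), 1 / (1 + 10^3.3), tolerance = 1e-12)
  expect_lt(fraction_neutral(7.4, mem), 6e-4)
  # half-ionisation at pH = pKa of the conjugate acid
  base <- toy_base_drug(pka_base = 8.6)
  expect_equal(fraction_neutral(8.6, base), 0.5)
  # limits: bases fully neutral at high pH, acids at low pH
  expect_gt(fraction_neutral(14, mem), 0.999)
  acid <- new_drug(list(name = "toy-acid", mw = 300, logp = 1, pka_acid = 4.5,
                        pka_base = NA, fu_p = 1, fu_b = 1, kpuu_bbb = 1,
                        kpuu_lv = 1, kpuu_lumbar = 1, ic50_unbound = 1))
  expect_gt(fraction_neutral(0, acid), 0.999)
  expect_lt(fraction_neutral(14, acid), 1e-9)
  # monotone in pH for a monoprotic base
  fs <- fraction_neutral(seq(4, 10, by = 0.5), mem)
  expect_true(all(diff(fs) > 0))
})

test_that("Kp to Kpuu conversion corrects binding and pH partitioning", {
  chy <- load_physiology()
  # all corrections unity for an unbound neutral drug
  expect_equal(kp_to_kpuu(3.7, toy_neutral_drug(), chy), 3.7)
  # hand-arithmetic oracle: 10 * (0.05 / 0.5) / 1 = 1
  d <- toy_neutral_drug(fu_p = 0.5, fu_b = 0.05)
  expect_equal(kp_to_kpuu(10, d, chy), 1)
  # a base concentrates in the more acidic ICF: D > 1 shrinks Kpuu
  b <- toy_base_drug(pka_base = 8.6)
  r <- fraction_neutral(chy$ph_ecf, b) / fraction_neutral(chy$ph_icf, b)
  expect_gt(chy$f_ecf + chy$f_icf * r, 1)
  expect_lt(kp_to_kpuu(10, b, chy), 10 * b$fu_b / b$fu_p)
  # scale equivariance
  expect_equal(kp_to_kpuu(2 * 10, b, chy), 2 * kp_to_kpuu(10, b, chy))
  nofu <- b
  nofu$fu_b <- NA_real_
  expect_error(kp_to_kpuu(10, nofu, chy),
               class = "cnspbpk_parameterization_error")
})

test_that("species scaling of asymmetry factors flips direction below unity", {
  # no scaling: unchanged
  expect_equal(scale_asymmetry_species(4, "efflux", numeric(0)),
               list(af = 4, direction = "efflux"))
  # halved magnitude, no flip
  expect_equal(scale_asymmetry_species(4, "efflux", c(pgp = 0.5)),
               list(af = 2, direction = "efflux"))
  # rat efflux 1/0.482 scaled by 0.22 * 1.1 drops below 1 and flips to influx
  res <- scale_asymmetry_species(1 / 0.482, "efflux", c(pgp = 0.22, bcrp = 1.1))
  expect_equal(res$direction, "influx")
  expect_equal(res$af, 1 / ((1 / 0.482) * 0.22 * 1.1), tolerance = 1e-12)
  expect_gt(res$af, 1.9)
  expect_lt(res$af, 2.1)
  # round trip with the reciprocal map is the identity when no flip occurs
  fwd <- scale_asymmetry_species(4, "efflux", c(a = 0.5))
  back <- scale_asymmetry_species(fwd$af, fwd$direction, c(a = 2))
  expect_equal(back$af, 4, tolerance = 1e-12)
  expect_equal(back$direction, "efflux")
  # across a flip the direction reversal makes the same map its own inverse
  flip <- scale_asymmetry_species(3, "influx", c(a = 0.25))
  expect_equal(flip$direction, "efflux")
  unflip <- scale_asymmetry_species(flip$af, flip$direction, c(a = 0.25))
  expect_equal(unflip$af, 3, tolerance = 1e-12)
  expect_equal(unflip$direction, "influx")
  expect_error(scale_asymmetry_species(2, "influx", c(a = -1)),
               class = "cnspbpk_domain_error")
  expect_error(scale_asymmetry_species(0.5, "influx"),
               class = "cnspbpk_domain_error")
})
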