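# Shared fixtures: toy drugs and physiology variants built in code.

# a drug with no ionisable groups and neutral Kpuu targets
toy_neutral_drug <- function(kpuu = 1, logp = 1, mw = 300,
                             fu_p = 1, fu_b = 1, ic50 = 10) {
  new_drug(list(
    name = "toy-neutral", mw = mw, logp = logp,
    pka_acid = NA, pka_base = NA,
    fu_p = fu_p, fu_b = fu_b,
    kpuu_bbb = kpuu, kpuu_lv = kpuu, kpuu_lumbar = kpuu,
    ic50_unbound = ic50
  ))
}

toy_base_drug <- function(pka_base = 9, kpuu = 1, logp = 2, mw = 300) {
  new_drug(list(
    name = "toy-base", mw = mw, logp = logp,
    pka_acid = NA, pka_base = pka_base,
    fu_p = 0.5, fu_b = 0.2,
    kpuu_bbb = kpuu, kpuu_lv = kpuu, kpuu_lumbar = kpuu,
    ic50_unbound = 10
  ))
}

# a mono-exponential single-compartment decay profile on a fine grid
exp_decay_profile <- function(k, c0 = 100, tau = 720, n = 721,
                              compartment = "brain_ECF") {
  t <- seq(0, tau, length.out = n)
  new_profile(tibble::tibble(time = t, compartment = compartment,
                             conc = c0 * exp(-k * t)))
}
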