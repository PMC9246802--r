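# Shipped drug registry: physicochemical and biological parameters, unbound
# empirical plasma PK models and clinical dosing regimens for the five
# modelled drugs. Plasma parameters are apparent values corrected for plasma
# protein binding (unbound scale): CL/Q in mL/min, V in mL, ka in 1/min.
# ic50_unbound in ng/mL. Kpuu values are unbound partition-coefficient
# targets used to calibrate barrier asymmetry factors; kpuu_bbb_species
# records whether the BBB value is a rat microdialysis measurement (then
# translated to human via transporter expression ratios) or a human value.
donepezil:
  mw: 379.49
  logp: 4.14
  pka_acid: 17.02
  pka_base: 8.62
  fu_p: 0.07
  fu_b: 0.107
  kpuu_bbb: 0.482
  kpuu_bbb_species: rat
  kpuu_lv: 1.8
  kpuu_lumbar: 1.8
  ic50_unbound: 0.57          # acetylcholinesterase, corrected for fu_b
  target: acetylcholinesterase
  transporter_substrate: [pgp, bcrp, cht]
  species_scaling: {pgp: 0.22, bcrp: 1.1}   # human:rat expression ratios
  plasma: {cl_cen: 2048, q_cen_per1: 0, v_cen: 391000, v_per1: 0, ka: 0.022, f_rel: 1}
  regimen: {dose: 10, interval: 1440}       # 10 mg once daily
galantamine:
  mw: 287.35
  logp: 1.16
  pka_acid: 14.81
  pka_base: 8.58
  fu_p: 0.83
  fu_b: 0.333
  kpuu_bbb: 0.826
  kpuu_bbb_species: human
  kpuu_lv: 1.2
  kpuu_lumbar: 1.2
  ic50_unbound: 55            # acetylcholinesterase, corrected for fu_b
  target: acetylcholinesterase
  transporter_substrate: []
  species_scaling: {}
  plasma: {cl_cen: 192, q_cen_per1: 510, v_cen: 157000, v_per1: 59000, ka: 0.051, f_rel: 1}
  regimen: {dose: 10, interval: 720}        # 10 mg twice daily
memantine:
  mw: 179.3
  logp: 3.31
  pka_acid: .na
  pka_base: 10.7
  fu_p: 0.55
  fu_b: 0.071
  kpuu_bbb: 2
  kpuu_bbb_species: rat       # human brain:plasma ratio similar to rat; no expression scaling
  kpuu_lv: 0.89
  kpuu_lumbar: 0.89
  ic50_unbound: 109           # NMDA receptor
  target: nmda_receptor
  transporter_substrate: [octn1]
  species_scaling: {}
  plasma: {cl_cen: 228, q_cen_per1: 0, v_cen: 194000, v_per1: 0, ka: 0.005, f_rel: 1}
  regimen: {dose: 20, interval: 1440}       # 20 mg once daily
rivastigmine:
  mw: 250.3
  logp: 2.45
  pka_acid: .na
  pka_base: 8.89
  fu_p: 0.6
  fu_b: 0.376
  kpuu_bbb: 0.733
  kpuu_bbb_species: rat       # preclinical asymmetry used directly
  kpuu_lv: 0.663
  kpuu_lumbar: 0.663
  ic50_unbound: 857.2         # acetylcholinesterase, corrected for fu_b
  ic50_secondary: 9.3         # butyrylcholinesterase (dual inhibition)
  target: acetylcholinesterase
  transporter_substrate: [cht]
  species_scaling: {}
  plasma: {cl_cen: 3333, q_cen_per1: 0, v_cen: 236000, v_per1: 0, ka: 0.052, f_rel: 1.4}
  regimen: {dose: 6, interval: 720}         # 6 mg twice daily (F = 1.4 at this dose)
semagacestat:
  mw: 361.4
  logp: 0.44
  pka_acid: 11.91
  pka_base: -3.7              # conjugate-acid pKa far below physiological pH: effectively non-ionisable
  fu_p: 0.382
  fu_b: 0.413
  kpuu_bbb: 0.55              # assumed equal to kpuu_lumbar
  kpuu_bbb_species: human
  kpuu_lv: 0.55
  kpuu_lumbar: 0.55
  ic50_unbound: 5.4           # gamma-secretase
  target: gamma_secretase
  transporter_substrate: []
  species_scaling: {}
  plasma: {cl_cen: 846, q_cen_per1: 0, v_cen: 71700, v_per1: 0, ka: 0.012, f_rel: 1}
  regimen: {dose: 140, interval: 1440}      # 140 mg once daily
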