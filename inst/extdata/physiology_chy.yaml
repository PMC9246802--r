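# Reference CNS physiology: cognitively healthy young adult (CHY).
#
# Internal units are fixed: volumes mL, flows mL/min, surface areas cm2,
# pH units, density g/mL. Provenance per field:
#   literature-default : standard human CNS physiology value (the model's own
#                        reference set; fully overridable)
# Fractions of brain volume for extracellular/intracellular fluid and the
# phospholipid binding phase are the published reference values (0.2 / 0.8 /
# 0.05 of brain volume).
physiology:
  population: CHY
  age: 35
  brain_volume: 1400          # mL, total brain tissue (literature-default)
  f_ecf: 0.2                  # brain ECF volume fraction (reference value)
  f_icf: 0.8                  # brain ICF volume fraction = 1 - f_ecf
  v_microvasc: 40             # mL, brain microvascular blood (literature-default)
  f_phospholipid: 0.05        # phospholipid binding phase, fraction of brain volume
  v_lysosome: 11.2            # mL, ~1% of brain ICF (literature-default)
  v_lv: 25                    # mL, lateral ventricles
  v_tfv: 3                    # mL, third + fourth ventricles
  v_cm: 7.5                   # mL, cisterna magna
  v_sas: 140                  # mL, subarachnoid space incl. cranial + spinal/lumbar CSF
  q_cbf_norm: 50              # mL/min/100 g, normalised cerebral blood flow
  q_cbf_total: 731.5          # mL/min = q_cbf_norm * brain mass / 100
  q_ecf_bulk: 0.175           # mL/min, brain ECF (interstitial) bulk flow
  q_csf: 0.35                 # mL/min, CSF production (~500 mL/day)
  sa_bbb: 150000              # cm2, blood-brain barrier surface area (~15 m2)
  sa_bcsfb: 75000             # cm2, blood-CSF barrier (choroid plexus), ~half of BBB
  bcsfb_split: 0.5            # fraction of sa_bcsfb facing the lateral ventricles
  sa_cell: 3.0e+06             # cm2, brain cell membrane area (ECF-ICF exchange)
  sa_lysosome: 6.0e+05         # cm2, lysosomal membrane area
  f_paracellular_bbb: 1.0     # relative paracellular permeability multiplier, BBB
  f_paracellular_bcsfb: 1.0   # relative paracellular permeability multiplier, BCSFB
  transporter_activity:       # relative activity per transporter class
    pgp: 1.0
    bcrp: 1.0
    cht: 1.0
    octn1: 1.0
  ph_plasma: 7.4
  ph_ecf: 7.3
  ph_icf: 7.0
  ph_lyso: 5.0
  ph_csf: 7.3
  brain_density: 1.045        # g/mL
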