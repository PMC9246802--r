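# cnspbpk

Physiologically based pharmacokinetic (PBPK) simulation of **unbound
small-molecule drug distribution in the human brain and cerebrospinal
fluid**, with physiology translation from cognitively healthy young adults
(CHY) to the cognitively healthy elderly (CHE) and to mild Alzheimer's
disease (AD).

## Who this is for

CNS drug developers and clinical pharmacologists who need unbound
concentrations at the brain target sites — brain extracellular fluid
(brain_ECF) and intracellular fluid (brain_ICF) — which cannot be sampled
in humans, and who want to know how well the one accessible fluid (lumbar
subarachnoid CSF, CSF_SAS) stands in for them, in health, in aging, and in
Alzheimer's disease.

## The model

Nine compartments: plasma (an empirical 1-/2-compartment oral model on the
unbound scale, used as a forcing function) plus eight CNS states — brain
microvascular blood, brain_ECF, brain_ICF, lysosomes, and the CSF chain
(lateral ventricles → third/fourth ventricles → cisterna magna →
subarachnoid space → venous absorption). The CNS is a linear mass-balance
system

```
dA/dt = M A + b Cp(t)
```

whose coefficients are built from physiology and drug properties:

* paracellular diffusion across the blood–brain barrier (BBB) and
  blood–CSF barrier (BCSFB), `P ∝ MW^(-1/3)`;
* transcellular permeation by the neutral species
  (Henderson–Hasselbalch pH partitioning per compartment), with
  `log10 P_trans = -4.0 + 0.45 logP` (cm/min at MW 350);
* directional **asymmetry factors** (AF ≥ 1) on transcellular clearance
  encoding net active transport, calibrated by root finding so the
  steady-state unbound compartment:plasma ratio hits the drug's
  K<sub>p,uu</sub> targets (K<sub>p,uu,BBB</sub>, K<sub>p,uu,LV</sub>,
  K<sub>p,uu,lumbar</sub>); rat-derived targets are translated to human via
  transporter expression ratios, flipping direction if the scaled factor
  crosses 1;
* ECF bulk (glymphatic) flow and the CSF production flow, the CNS
  elimination routes;
* nonspecific tissue binding to the phospholipid phase as apparent
  volumes, re-derived across populations from the phospholipid fraction;
* lysosomal ion trapping of bases from the ICF–lysosome pH difference.

Population translation applies literature-derived aging rates (e.g. brain
−0.401%/year, ventricles +3.45%/year from age 60, compounded) and mild-AD
fold changes (e.g. brain ×0.95, ECF fraction ×1.4, BBB paracellular ×4.4)
to the CHY reference set. A registry ships the five modelled drugs
(donepezil, galantamine, memantine, rivastigmine, semagacestat) with
physicochemistry, unbound plasma PK, dosing regimens and unbound IC50s.

## Worked example

Semagacestat (a gamma-secretase inhibitor that failed in trials), 140 mg
once daily, mild-AD physiology at age 70:

```r
library(cnspbpk)

ad    <- build_population("AD", age = 70)
drug  <- load_drug("semagacestat")
model <- build_model(ad, drug)
tidy(model)
#> # A tibble: 3 × 6
#>   barrier   af_in af_ef theta kpuu_target achieved
#> 1 BBB           1  1.83 0.547        0.55    0.55
#> 2 BCSFB_LV      1  1.76 0.568        0.55    0.550
#> 3 BCSFB_TFV     1  1.82 0.549        0.55    0.55

ss <- run_to_steady_state(model)
compute_metrics(ss, c("brain_ECF", "brain_ICF", "CSF_SAS"))
#> # A tibble: 3 × 8
#>   compartment  cmax     cmin  tmax auc_tau  cavg half_life fluctuation
#> 1 brain_ECF    317.  0.00231  150.  91017.  63.2      64.0    136764.
#> 2 brain_ICF    316.  0.00245  155.  91015.  63.2      64.0    129121.
#> 3 CSF_SAS      139. 10.5      295.  91017.  63.2     274.         13.3

engagement(ss, drug$ic50_unbound, c("brain_ECF", "CSF_SAS"))
#> # A tibble: 2 × 6
#>   compartment fraction_above n_crossings drug_free_onset always_above
#> 1 brain_ECF            0.488           2            708. FALSE
#> 2 CSF_SAS              1               0             NA   TRUE
```

Reading: a K<sub>p,uu</sub> of 0.55 (< 1) calibrates to net efflux at both
barriers. At steady state the brain target-site profile swings five orders
of magnitude within each dosing interval (Cmax:Cmin ≈ 1.4×10⁵) and falls
below the unbound IC50 (5.4 ng/mL) at ≈ 11.8 h post dose — the brain is
effectively drug-free for half of every day — while the slowly-turning-over
subarachnoid CSF barely fluctuates (Cmax:Cmin ≈ 13) and never drops below
the IC50. A lumbar sample would look continuously "therapeutic" while the
target site is not: CSF is an unreliable surrogate of brain PK.

Other entry points: `case_study_1()` (four marketed AD drugs vs their
target IC50s), `case_study_2()` (the semagacestat contrast above, CHY vs
AD), `compare_populations()` (CHY/CHE/AD exposure fold changes),
`oat_sensitivity()` (one-at-a-time parameter perturbations),
`generate_drug()`/`generate_observations()` (synthetic inputs), and a thin
command-line wrapper at `inst/cli/cnspbpk.R`.

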