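---
title: "Modelling unbound drug distribution in brain and CSF: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling unbound drug distribution in brain and CSF: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnspbpk)
```

# The problem

Unbound drug concentration at the target site drives pharmacological
effect, but the human brain cannot be sampled: microdialysis is ethically
restricted, imaging does not separate bound from unbound drug, and lumbar
CSF — the one accessible fluid — is a questionable surrogate for brain
extracellular fluid. `cnspbpk` simulates the unbound concentration-time
profiles of small molecules in the compartments that matter (brain ECF and
ICF, the target sites; subarachnoid CSF, the sampling site) from first
principles: drug physicochemistry, CNS anatomy and physiology, and an
empirical unbound plasma input. Because every coefficient is a physiological
quantity, the same model translates across populations — here from
cognitively healthy young adults (CHY) to the cognitively healthy elderly
(CHE) and to mild Alzheimer's disease (AD).

# Model structure

Nine compartments: plasma (a forcing function, no feedback — CNS
distribution is a negligible mass fraction of any dose), brain microvascular
blood, brain ECF, brain ICF, lysosomes, and the four-compartment CSF chain
(lateral ventricles LV, third+fourth ventricles TFV, cisterna magna CM,
subarachnoid space SAS including the lumbar region). The eight CNS states
form a linear mass-balance system $\dot A = M A + b\,C_p(t)$ in drug
amounts, integrated with `deSolve::lsoda` at relative tolerance $10^{-8}$.

Transport routes:

* **BBB and BCSFB, paracellular**: symmetric aqueous diffusion,
  $CL = f_{para} \cdot P_{para}(MW) \cdot SA$, with
  $P_{para} \propto MW^{-1/3}$ (cube-root diffusion scaling) anchored at
  $10^{-8}$ cm/s for MW 350. The BCSFB surface is split between an
  LV-facing and a TFV-facing face (50/50 by default, configurable).
* **BBB and BCSFB, transcellular**: carried by the neutral species on the
  donor side (pH partitioning à la Henderson–Hasselbalch, at most one
  acidic and one basic group per drug), with directional asymmetry factors
  for active transport (below).
* **Cell membranes**: brain ECF–ICF and ICF–lysosome exchange, neutral
  species only; this produces ion trapping of bases in the more acidic ICF
  and, strongly, in lysosomes (at steady state the lysosome:ICF unbound
  ratio equals $f_n(pH_{ICF})/f_n(pH_{lyso})$ exactly).
* **Fluid flows**: ECF bulk (glymphatic) flow out of brain ECF into the
  CSF, and the CSF production flow running LV → TFV → CM → SAS → venous
  absorption (the only true CNS elimination route besides back-transport to
  blood).
* **Tissue binding**: instantaneous equilibrium to the phospholipid phase,
  implemented as apparent volumes $V_{app} = V / f_{u,eff}$ for ICF and
  lysosomes. Across populations $f_{u,eff}$ is re-derived from the
  phospholipid volume fraction (binding capacity $\propto$ phospholipid
  fraction), so AD's phospholipid loss raises the unbound fraction.

The governing equations of the original modelling line are not public in
the primary report, so this system is this package's own concrete,
documented design; all coefficients are inspectable via
`clearance_table()`.

## The transcellular permeability map

$\log_{10} P_{trans}\,[\mathrm{cm/min}] = -4.0 + 0.45\,\log P$, scaled by
$(350/MW)^{1/3}$. The intercept and slope were fixed once so that a logP 2
drug sits at $\approx 1.3\times10^{-5}$ cm/s, the middle of the passive BBB
permeability range reported for in-situ perfusion data. Steady-state
compartment **ratios** are insensitive to this map because the asymmetry
factors are calibrated on top of it (any barrier-level error is absorbed by
construction); absolute equilibration **rates** — peak times, fluctuation,
time below IC50 — are sensitive to it, which is stated openly wherever
those quantities are reported.

## Asymmetry factors and Kpuu calibration

Net active transport at a barrier is encoded as a directional multiplier
$AF \ge 1$ on the transcellular clearance (transporters are membrane
proteins; the paracellular route is symmetric and AF-free). Each barrier's
AF is calibrated by 1-D root finding so that, under a constant unit unbound
plasma infusion, the steady-state unbound compartment:plasma ratio equals
the drug's Kpuu target within $10^{-3}$: Kpuu,BBB at brain ECF, Kpuu,LV at
the LV, and Kpuu,lumbar at the TFV face. Calibration runs in the full
steady-state system, so it automatically compensates competing processes —
with ECF bulk flow active, a Kpuu,BBB of 2 requires $AF_{in} > 2$. Targets
above the reachable range (AF capped at $10^6$) raise a calibration error
that reports the achievable ratio interval.

Rat-derived BBB Kpuu values are calibrated in place and then translated to
human by multiplying the directional AF magnitude by the product of
human:rat transporter expression ratios for the transporters the drug is a
substrate of; if the scaled magnitude falls below 1 the net direction flips
and the magnitude is reciprocated (donepezil's rat net efflux of ~2 becomes
a human net influx of ~2 under the 0.22 x 1.1 P-gp/BCRP ratios).

## ECF bulk-flow routing

The bulk flow drains into the CSF; its entry compartment is configurable
(`CSF_LV`, `CSF_CM`, `CSF_SAS`). The default is **CSF_LV**: entering
upstream of both calibrated BCSFB faces means the calibrated ventricular
and lumbar ratios propagate down the CSF chain unchanged, so the
subarachnoid (sampling-site) steady-state ratio equals Kpuu,lumbar for
every drug. Entry at the cisterna magna would inject brain-level
concentrations downstream of both calibration points and distort the
sampling-site ratio whenever Kpuu,BBB differs from Kpuu,lumbar (about +30%
for memantine, 2 vs 0.89). Downstream of the entry point the chain flow is
the CSF production flow plus the bulk flow (fluid conservation).

# Reference physiology and population translation

The shipped CHY set uses the published reference fractions (ECF 0.2, ICF
0.8, phospholipid 5% of brain volume) and literature-standard values for
the remaining anatomy (1400 mL brain, CSF 25/3/7.5/140 mL for LV/TFV/CM/
SAS, CSF production 0.35 mL/min, ECF bulk flow 0.175 mL/min, BBB 15 m²,
BCSFB 7.5 m², pH 7.4/7.3/7.0/5.0/7.3 for plasma/ECF/ICF/lysosome/CSF).
Every field carries a provenance label and is fully overridable through the
YAML configuration; `validate_physiology()` reports violated invariants
(positivity, fraction complements, total-vs-normalised CBF consistency
within 0.1%).

Aging (from 60 years): per-year rates compound multiplicatively,
$x(a) = x(60)(1 \pm r)^{a-60}$ — brain −0.401%/y; ventricles +3.45%/y;
cisterna magna +1.09%/y; SAS +0.78%/y — with a linear alternative behind
`compounding = FALSE`. The phospholipid fraction declines piecewise
linearly (−10% over 60→80, a further −8% over 80→100). Quantities reported
as elderly-vs-young totals (ECF fraction −16%, ECF bulk flow −33%, BBB
surface −10%) are phased in linearly over ages 60–80 so that physiology is
continuous at the onset age, mirroring the banded phospholipid treatment.
Normalised CBF is age-invariant; total CBF is recomputed on the shrunken
brain, and microvascular volume preserves the young
microvascular-volume:CBF ratio. Brain ICF pH drifts −0.001/y.

Mild AD (relative to age-matched CHE): brain ×0.95; ECF fraction ×1.4 (ICF
as complement); phospholipid ×0.90; ventricles ×1.39; extraventricular CSF
×1.21; normalised CBF ×0.85; ECF bulk flow ×0.85 (both atrophy-corrected);
BBB surface atrophy-corrected ×1.1123; BBB paracellular ×4.4; BCSFB
paracellular and CSF flow unchanged; lumbar CSF pH +0.018. "Corrected for
brain atrophy" is implemented as scaling by the atrophied:baseline volume
ratio before the population factor, consistently for CBF, bulk flow and
BBB surface. Brain ECF/ICF pH change in AD is reported only as a range
(0 to +0.009) with no consensus value, so the default shift is 0
(configurable). Only mild AD is parameterised; other severities raise an
explicit error, and AD factors refuse to compose (they are CHE-relative).
Default simulation ages are 35 (CHY) and 70 (CHE and AD, age-matched);
these are package choices — the source analyses do not state simulation
ages — and are arguments everywhere.

# Plasma input and steady state

Plasma is an empirical 1- or 2-compartment oral model on the unbound scale,
solved in closed form via its exponential modes (matrix eigenvalues for the
2-compartment case; the $ka \to ke$ degenerate limit uses the $t e^{-kt}$
form). Superposition gives finite multi-dose profiles; the periodic steady
state is the mode-wise geometric series. `plasma_closed_form_check()`
verifies the closed form against an independent `lsoda` integration to
better than $10^{-8}$.

`run_to_steady_state()` integrates the CNS system interval by interval
under the steady-state plasma forcing until every compartment's interdose
AUC changes by less than 0.5% between consecutive intervals (and at least
five plasma terminal half-lives are covered). Chronic runs warm-start at
the constant-infusion steady state matching the average plasma level —
exact for the interval averages of a linear system — so the iteration only
equilibrates the periodic ripple. Without this, deep depots fill on their
own timescale (memantine's lysosomal trapping, unbound lyso:ICF ratio
$\approx 100$, gives the CNS a multi-week terminal mode) and a
successive-interval criterion can declare convergence far from the periodic
orbit.

# Metrics, engagement and sensitivity

`compute_metrics()` reports Cmax, Cmin, Tmax (grid scan with local
parabolic refinement), interval AUC (trapezoid), fluctuation (Cmax:Cmin)
and the terminal half-life from a log-linear fit over the last 30% of the
interval past Tmax (undefined, not an error, if the tail is non-positive).
`engagement()` interpolates IC50 crossings linearly, integrates the
fraction of the interval at or above the IC50, and defines the drug-free
onset as the first downward crossing with no later upward crossing.
"Drug-free" is operationalised as below the unbound IC50; `case_study_1()`
additionally reports whether the plateau (interval-average) concentration
exceeds the IC50, since a profile can dip briefly below the IC50 between
doses while remaining "above" in the plateau sense.

`oat_sensitivity()` perturbs one physiological parameter at a time (×2 and
×10 with reciprocals; ±1 and ±2 pH units for pH fields) on the assembled
model with asymmetry factors frozen at their reference calibration —
re-calibrating would cancel barrier perturbations by construction
(`recalibrate = TRUE` is available). Perturbed sets are checked only for
structural validity (positivity, fractions < 1): the ±2 pH scheme leaves
the loader's physiological plausibility band by design. Percent change is
$100(x' - x)/x$.

# Synthetic data

`generate_drug()` draws physically consistent random drug records (logP in
[−1, 5], MW in [150, 600], optional basic/acidic group, log-uniform unbound
fractions and Kpuu targets) for property-based testing without any external
data; `generate_observations()` emulates sparse clinical CSF sampling with
multiplicative log-normal noise (CV 20% by default, median-unbiased).
What the generator emulates — and what it does not: draws are single
deterministic parameter vectors, not virtual populations; there is no
parameter correlation structure, no inter-individual variability and no
assay limit of quantification. Tests passing on synthetic drugs therefore
demonstrate numerical and structural correctness of the pipeline, not
predictive accuracy for real compounds.

# Numerical choices and problem sizes

* Integration: `lsoda`, rtol $10^{-8}$, amount-scaled atol; the
  microvascular compartment (small volume, full CBF) makes the system
  stiff, which `lsoda` handles automatically.
* Calibration: `uniroot` on $\log_{10} AF \in [-6, 6]$, tolerance well
  below the $10^{-3}$ contract.
* Default grids: 1001 points per interdose interval for simulation (the
  acceptance script uses 2001); metrics are stable to < 0.1% beyond ~1000
  points.
* Steady state: 0.5% interdose-AUC tolerance, far below any reported
  population effect size.
* Degenerate absorption ($|ka - ke| < 10^{-9}$): exact limit form in the
  1-compartment case, an infinitesimal rate nudge in the 2-compartment
  case.

# Known limitations

* No regional brain resolution (grey/white matter are collapsed into
  weighted scalars); no saturable transport, target-mediated disposition or
  brain metabolism.
* The absolute transcellular permeability map is a design choice; absolute
  rates inherit its uncertainty while calibrated steady-state ratios do
  not.
* Population translations are knowledge-based fold changes, not fits to
  clinical CNS PK data (none exist for these populations); predictions are
  "as accurate as" the underlying literature physiology.
* The lumbar site is not resolved as a sub-compartment of the subarachnoid
  space; Kpuu,lumbar is applied at the TFV face and inherited by the SAS
  through the CSF chain.

# A worked example

```{r example, eval = FALSE}
library(cnspbpk)

ad <- build_population("AD", age = 70)
drug <- load_drug("semagacestat")
model <- build_model(ad, drug)
tidy(model) # calibrated asymmetry factors and achieved ratios

ss <- run_to_steady_state(model)
compute_metrics(ss, c("brain_ECF", "CSF_SAS"))
engagement(ss, drug$ic50_unbound, c("brain_ECF", "CSF_SAS"))
autoplot(ss, ic50 = drug$ic50_unbound)
```
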