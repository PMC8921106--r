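---
title: "Methods: a chlordecone PBPK model for rats and humans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a chlordecone PBPK model for rats and humans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdpbpk)
```

## Why a PBPK model for chlordecone

Chlordecone (CD, Kepone) is a persistent organochlorine insecticide whose
use in banana farming left soils and food chains of the French West Indies
contaminated decades after its withdrawal. Blood CD concentration is the
practical biomarker of chronic exposure, because the compound's blood
half-life is on the order of months; translating a measured blood
concentration into the external oral dose that sustains it (reverse
dosimetry) requires a kinetic model. `cdpbpk` implements a
physiologically based pharmacokinetic (PBPK) model of CD for the rat — the
species with the richest experimental record — and for the human, with the
species difference expressed entirely through parameters.

## Model structure

The body is divided into seven compartments: lung, blood, brain, skin,
adipose tissue, liver, and a rest-of-body pool that closes the mass
balance, plus an extravascular lipoprotein/lymphatic (ELPLC) pathway
carrying part of the intestinal uptake directly to venous blood. Brain,
skin, adipose and liver are *permeability-limited*: each is split into a
tissue-blood sub-compartment, perfused at its share of cardiac output, and
a cellular matrix exchanging with tissue blood through a permeability-area
product `PA` (L/h). Lung and rest-of-body are flow-limited.

Three rules shape the kinetics:

* **Blood binding.** A fixed fraction `BIND` of blood CD is bound to
  albumin/HDL; binding is linear (not saturable). Only the free fraction
  `1 - BIND` leaves the blood, so every uptake and clearance flux is
  driven by `C_free = (1 - BIND) * A_blood / V_blood`.
* **Aqueous-activity convention.** Partition coefficients `P` are
  tissue:blood ratios; the thermodynamically active concentration inside a
  tissue is `C_tissue_free / P`. Exchange fluxes are written
  `PA * (C_tissue_blood - C_tissue_free / P)`, and hepatic elimination and
  protein binding are driven by the same blood-equivalent quantity. This
  is the standard venous-equivalent clearance convention; it makes the
  liver partition a pure storage parameter, which matters for the
  sensitivity results below.
* **Hepatic sequestration.** Liver cytosol contains chlordecone-binding
  proteins (CDBP). Bound liver concentration is saturable,
  `LIBMAXCD1 * x / (KD_LIV + x)` with `x` the blood-equivalent free
  concentration, and `x` is recovered from the total tissue amount by
  solving the resulting quadratic. At survey-scale exposures
  (`x << KD_LIV`) the binding is linear and the apparent liver:blood
  ratio is `P_liver + LIBMAXCD1/KD_LIV`; at poisoning-scale doses the
  binding saturates. The observed liver/fat concentration ratio of 5-10 —
  far above what lipid partitioning alone would give — emerges from this
  term.

### The gut and the enterohepatic cycle

The lumen has three pools. An oral dose lands almost entirely in the
absorbing proximal segment (`f_prox = 0.98`); uptake is first-order with
flux `KA * k_abs * A`, in competition with transit `KST * A` to the
distal segment, which does not absorb and empties into faeces at `k_fec`.
With the shipped constants about 90% of an oral dose is absorbed, and the
absorbed flux splits `f_lymph` to the ELPLC (bypassing first pass) and the
remainder to the liver via the portal vein.

Biliary output of parent CD re-enters the absorbing pool with probability
`F_reab` (0.95 in the human set); in humans a fraction `KBILE` of the
biliary output leaves as the reduced/conjugated metabolite (CD-OH and its
glucuronide), of which a fraction `f_reconv` is deconjugated in the lumen,
reduced back to CD and rejoins the absorbable pool; the rest leaves in
faeces as metabolite. Rats lack chlordecone reductase, so the rat set has
`KBILE = 0` and the metabolite pathway is inert. An enteric excretion
clearance `k_ent` moves CD from blood directly into the distal (purely
excretory) segment; the literature's statement that this flux is not
reabsorbed is directionally odd — secretion "before the region of
reabsorption" would be reabsorbed — so the model routes it distally and
treats it as purely excretory, which is what the kinetic evidence
supports.

A design note on `f_reconv`: with complete reconversion (`f_reconv = 1`)
the metabolite split `KBILE` cancels out of the mass balance entirely —
every biliary molecule returns to the same absorbable pool regardless of
its chemical form — and the model could never show `KBILE` as a sensitive
parameter, nor metabolite in human faeces, both of which are well
established. The human default is therefore `f_reconv = 0.9`
("mostly, not entirely, reconverted").

### Exposure routes

Oral gavage is an instantaneous lumen bolus; dietary exposure is a
continuous zero-order lumen input (animals feed throughout the day; the
two representations agree at steady state to within ~2%); intravenous
doses enter blood directly. Dermal and inhalation parameters exist
structurally (`KP_derm`, `P_blood_air`, ...) but the routes ship disabled
and unvalidated, and scenario construction rejects them unless explicitly
allowed.

## Physiology and units

Internal units are µg, L and hours; doses are per kg body weight and are
converted with the body weight frozen at run start (no growth during a
simulation; age enters through `physiology_at_age()`). Cardiac output and
alveolar ventilation scale allometrically, `QC = 15 * BW^0.74` L/h. The
default growth model is "static adult" (rat 0.25 kg, human 70 kg), because
every anchor this package reproduces uses adult animals or subjects;
age-resolved polynomial tables can be supplied through `growth_model()`
and a config file. Named compartment volumes are fractions of body weight;
the rest-of-body absorbs the remainder up to a perfused total of 91% of
body weight (bone and hair are not perfused).

## Numerical choices

The stiff `lsoda` integrator is used with relative tolerance 1e-8 and
absolute tolerance 1e-12 µg. The timeline is split at every bolus event
and at dietary-rate boundaries, restarting the integrator at each
discontinuity, so no dosing discontinuity is ever stepped over. A
mass-balance ledger (administered = in body + faeces + urine) is checked
at every output time with a 1e-6 relative tolerance; violation is an
error, not a warning. Tiny negative amounts within solver round-off are
clamped to zero for reporting. The liver free concentration takes the
non-negative root of the binding quadratic. "Blood concentration" always
means whole-blood total (free + bound), because the measured anchors are
whole-blood/plasma totals; plasma and whole blood are treated as
equivalent (no haematocrit correction).

## Calibration

The model's absolute scale cannot be fixed from structure alone, so both
species sets are pinned to published summary anchors rather than to raw
time-series (which are not reproduced here; the fixtures module emulates
the study designs instead).

* **Rat.** `CL_bile`, `k_urine`, `PA_adipose`, `F_reab`, `k_ent`,
  `LIBMAXCD1` and `P_adipose` were tuned (derivative-free optimisation on
  the log scale) so that a single oral 40 mg/kg bw dose in a 0.25-kg rat
  yields a 21-day blood half-life on the day 14-56 window, 60% of the dose
  in faeces and 1.5% in urine at day 84. The solution is strongly
  multiphasic: a very slow adipose permeability (`PA_adipose` of order
  1e-3 L/h) lets fat accumulate over weeks and hold the body burden while
  blood declines faster — which is exactly what the classical excretion
  balance demands, since a single 21-day phase would have eliminated ~94%
  of the dose by day 84.
* **Human.** `calibrate_human_scale()` iterates two coordinate steps: the
  irreversible elimination constants (`CL_bile`, `k_urine`, `k_ent`) are
  rescaled jointly — preserving their ratios — until the steady-state
  anchor pair (blood 0.42 µg/L at 0.007 µg/kg bw/day, 1000-day exposure)
  is met, and the adipose partition is adjusted as the
  volume-of-distribution lever until the terminal half-life on the day
  300-900 post-cessation window is 131 days. The shipped
  `human_params()` are the converged output, so re-running the
  calibration is idempotent (it converges in one round with sub-0.1%
  changes). All other printed quantities — the reverse-dosimetry doses for
  1.03, 0.52, 1.48 and 0.04 µg/L, the liver/fat ratio — are out-of-sample
  predictions of the calibrated model, reproduced by
  `scripts/acceptance.R`.

The likelihood used by `fit_cd()` is the proportional-error Gaussian: each
record contributes
`-log(sigma*pred*sqrt(2*pi)) - (obs - pred)^2 / (2*sigma^2*pred^2)`, and
left-censored records contribute the Gaussian mass below the detection
limit. The per-matrix `sigma` is profiled as the root-mean-square relative
residual unless fixed. One algebraic subtlety is worth recording: because
the error SD scales with the prediction, the likelihood as a function of
the *prediction* peaks at `obs/(1 + sigma^2)`, not exactly at `obs`; as a
function of the *observation* it peaks at `pred` exactly. The test suite
checks the property in the direction in which it is true.

Half-life windows are fixed conventions, not measurements: rat days 14-56
post-dose, human days 300-900 post-cessation. The underlying decay is
multiphasic (rat literature reports 8.5/24/45-day phases), so a "half-life"
is only reproducible once the window is stated.

## Sensitivity screen

The screen perturbs one parameter at a time by ±5% and reports
`SA% = 100 * (C_perturbed - C_baseline)/C_baseline`, with `C` the blood
concentration at day 655 of a constant oral exposure of 1e-3 µg/kg bw/day
(five half-lives, i.e. ~97% of plateau — deliberately short of full steady
state, so distribution-volume parameters retain a small, measurable
influence through the approach to plateau). The ±5% magnitude follows the
method's prose convention. Parameters whose larger-magnitude response
exceeds 0.2% form the sensitive set; with the shipped human configuration
these are exactly `BIND`, `KA`, `KBILE`, `KST`, `LIBMAXCD1` and
`P_adipose`, and they are also the top six by |SA%|.

The screened manifest (`sa_manifest()`, frozen at 40 entries) lists the
model's independently specified scalar inputs. Four groups of scalars are
deliberately *not* screened, each for a stated structural reason:
parameters that enter the equations only as one degree of freedom with a
screened partner in the linear regime (`k_abs` with `KA`, `KD_LIV` with
`LIBMAXCD1` — screening both members would double-count one direction);
the calibration-pinned scale constants (`CL_bile`, `F_reab`, `f_reconv`),
which are outputs of the anchor calibration rather than uncertain inputs —
and whose ±5% response is mathematically forced to ~5% times their
pathway share, so screening them reports the calibration, not the
biology; the constrained dose-split pair `f_prox`/`f_dist` (perturbing one
member alone violates their sum constraint); and body weight and the
storage-organ volumes, which come from the growth model rather than the
scalar roster. Local one-at-a-time screening is the method implemented;
no global (Morris/Sobol) indices are computed.

## Synthetic fixtures

`generate_timecourse_fixture()` reproduces the *designs* of the classical
studies (single IV 1 mg/kg; single oral 40 mg/kg with 182-day sampling and
urine on days 1-7 only; 3-day dietary; 90-day dietary at 5 ppm; 1000-day
occupational exposure at 0.19 mg/kg bw/day) by simulating the shipped
model at frozen sampling schedules and adding multiplicative lognormal
noise of relative SD `sigma_rel` (default 0.15, matching the relative-
error likelihood; the noise is mean-one, so `sigma_rel = 0` returns the
simulator output bit-for-bit). For the 90-day dietary design the printed
equivalent dose of 0.125 mg/kg bw/day is used; note that dimensional
arithmetic from the stated intake (5 ppm at 10 g food per 100 g bw) gives
0.5 mg/kg bw/day — `diet_ppm_to_dose()` computes the dimensional value,
and the discrepancy is left visible rather than hidden.

`generate_population_survey()` draws a lognormal-mixture population of
blood concentrations, censors below the 0.06 µg/L detection limit with
LOD/√2 imputation, and labels quartile groups with the 166/337/168 size
convention at n = 671. The default mixture is tuned so the three group
medians land near 0.04, 0.42 and 1.48 µg/L: the lowest-group median is
then the imputation value itself, as in the emulated survey. A single
lognormal cannot reproduce all three medians (the lower tail is fattened
by the below-LOD mass), hence the two-component default.

What passing tests on these fixtures does *not* show: agreement with the
historical measurements themselves (which are not shipped), inter-animal
variability (fixtures have one subject), assay-specific error structure,
or model misspecification — a fit to data generated by the model itself
can only demonstrate identifiability and correctness of the machinery.

## Problem sizes and runtime

All shipped analyses are desk-scale: a 1000-day stiff integration takes a
fraction of a second; the 40-parameter screen is 81 runs (~10 s); the
acceptance pipeline (calibration, four reverse-dosimetry inversions, the
182-day rat study, a 1900-day washout and a steady-state run) completes in
a few seconds; the parameter-recovery fits in the test suite use two free
parameters against a 51-record fixture.

## Known limitations

* CD-OH does not circulate systemically in the model (it is tracked in
  bile, lumen and faeces only), consistent with its near-absence from
  plasma and urine.
* Physiology is frozen during a simulation; lifetime exposure with growth
  requires stepping age externally.
* Dermal and inhalation routes are structural placeholders awaiting data.
* Reverse dosimetry returns point estimates; no uncertainty intervals.
* The rat terminal phase beyond the calibrated windows (week 14+) is an
  extrapolation of the fitted adipose exchange, not an independently
  anchored quantity.

## A worked example

```{r example, eval = FALSE}
phys <- physiology_at_age("human")
p <- calibrate_human_scale(human_params())

# what external dose sustains the prostate-cancer risk threshold of
# 1.03 ug/L?
reverse_dose(1.03, p, phys)$dose
#> [1] 0.0171715

# rat mass balance at day 84 after a single oral 40 mg/kg dose
sim <- simulate_cd(single_oral(mg_per_kg(40), species = "rat"),
                   rat_params(), physiology_at_age("rat"),
                   duration = days(182), times = days(seq(0, 182, 0.5)))
excretion_fractions(sim, 84)
#> faecal_pct urinary_pct  body_pct
#>       60.0         1.5      38.5
```
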