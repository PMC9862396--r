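---
title: "Model and methods: whole-body PBPK of tegoprazan and M1 with CYP-turnover DDIs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`tegopbpk` implements a whole-body physiologically based pharmacokinetic
(PBPK) model for the potassium-competitive acid blocker tegoprazan and its
desmethyl metabolite M1, together with the enzyme-turnover machinery needed
to simulate drug–drug interactions (DDIs) with CYP3A4 perpetrators.

**Distribution.** Fourteen compartments (adipose, bone, brain, heart,
kidney, muscle, skin, a lumped "rest", gut, spleen, liver, lung, arterial
and venous blood) are linked by plasma-equivalent blood flows
(blood-to-plasma ratio assumed 1). Distribution is perfusion-limited: each
organ exchanges at `Q_i (C_art - C_i / Kp_i)`, gut and spleen drain through
the liver (portal vein), and the lung sits in series between the venous and
arterial pools. Tissue-to-plasma partition coefficients come from a
published tissue-composition method (neutral-lipid / phospholipid / water
partitioning with a tissue unbound fraction estimated from plasma binding;
the adipose term uses the unbound-plasma form). The method label is
recorded on every result and per-organ overrides are accepted — the
upstream modelling platform's proprietary "standards" calculation is not
public, so the substitution is explicit. A perfusion-limited structure
makes `AUC_inf` independent of the Kp set; consequences for the
sensitivity analysis are discussed below.

**Absorption.** Oral doses deposit undissolved drug in the stomach.
Dissolution follows a Weibull law parameterised so that the printed
parameters keep their stated meaning,

  m(t) = 1 − exp(−ln 2 · (t / t50)^b),

which guarantees `m(t50) = 0.5` exactly (fasted: t50 = 0.942 h, b = 0.990;
fed: t50 = 4.23 h, b = 0.502). In the ODE the law enters as a hazard on the
undissolved pools, evaluated at the time since the most recent dose (each
dose restarts the dissolution clock; with once- or twice-daily regimens the
previous dose is essentially fully dissolved before the next one, so the
approximation is immaterial). The hazard is capped at 200 h⁻¹ to keep the
integrand finite for b < 1; the cap distorts only the first ~10⁻⁵ h after a
dose. The gastrointestinal tract is discretised as stomach, four
small-intestinal segments and a colon with first-order transit; dissolved
drug is taken up at `Peff × effective area` from the intestinal segments.
The colon absorbs by default: with the fitted Weibull parameters and
standard transit times an ileal cutoff would lose ~13% of a fasted and
~50% of a fed dose, which is incompatible with the model's own terminal
mass balance (pathways totalling ~99.6% of dose) — tegoprazan is a
high-permeability compound and the colonic contribution is what completes
absorption of the slowly dissolving fed-state dose. Set
`solver_options(colon_absorption = FALSE)` to restore the ileal cutoff.
Meals raise gastric pH to 5.5 and slow gastric emptying (default
multiplier 0.25), both relaxing back exponentially (default half-life
0.75 h, a configuration entry — the behaviour is described upstream, the
constant is not); fed doses use the fed dissolution parameter set.
pH-dependent solubility is available as a diagnostic
(`ionization_fraction()`) but is deliberately not wired into dissolution.

**Elimination.** Parent elimination comprises four first-order CYP
reactions in the liver — CYP3A4 and CYP2C19, each splitting into an M1
branch and an "other metabolites" branch with intrinsic clearances in
µL/min/pmol enzyme — plus a gut-wall copy of the two CYP3A4 reactions and
renal plasma clearance. Metabolic rates are
`clint × E × V_organ × 60` (L/h) applied to the unbound tissue plasma-water
concentration `fu · C_organ / Kp_organ`; this localises the intracellular-
unbound approximation in one place. Renal clearance (0.297 mL/min/kg) and
M1's lumped total hepatic plasma clearance (0.140 mL/min/kg) are applied to
arterial plasma, matching their definition as total plasma clearances
rather than organ-extraction models. M1 is formed molar-for-molar in liver
and gut tissue and distributed with its own Kp set. Because everything is
first order, the within-enzyme product split equals the clint ratio
exactly — an analytic oracle the tests exploit — and AUC is dose-linear.

**Units.** Internally µmol and hours; ng/mL at every interface via the
molecular weights (387.38 parent, 373.40 metabolite).

## Reference individual and enzyme abundances

The bundled physiology is a 73.5-kg reference adult male. That weight is
implied by the model's own renal-clearance conversion
(0.297 mL/min/kg ≙ 1.31 L/h) and makes the reported steady-state exposure
internally consistent through the exact identity
`AUC = f_renal · Dose / CL_renal`; building the same model at 50 kg would
contradict the reported AUC by ~45%. Volumes scale linearly with weight,
flows with weight^0.75; enzyme tissue concentrations are weight-invariant.

Absolute CYP abundances are not observable from plasma data, but the
eliminated-fraction split they imply is reported (71.6% CYP3A4, 20.2%
CYP2C19, 7.82% renal — shares that sum to 99.62 and are treated as
relative shares of total elimination).
`calibrate_enzyme_abundance()` pins the two hepatic reference
concentrations (the gut CYP3A4 concentration keeps a fixed expression
ratio of 0.15 to the liver) by a fixed-point iteration on the pathway odds
against renal excretion; each iteration is one terminal mass-balance
simulation and convergence takes 3–5 iterations. For a liver-only
configuration the resulting abundance ratio equals the analytic identity
`(fm1/fm2)·(ΣCLint2/ΣCLint1)` ≈ 4.83. The bundled `enzymes.yaml` stores
the calibrated values; the acceptance script recomputes them from a
neutral starting guess at run time.

Enzyme turnover half-lives are configuration entries (not reported
upstream): CYP3A4 36 h in liver and 23 h in gut mucosa, CYP2C19 26 h —
typical literature values. DDI magnitudes depend on them directly, which
is why they are stored in the config and echoed in provenance.

## The DDI engine

Enzyme pools follow `dE/dt = Rsyn − kdeg·E` with `Rsyn = E_ref·kdeg`.
Mechanism-based inactivation adds `kinact·I/(KI+I)` to the loss rate;
induction multiplies synthesis by `1 + Emax·I/(EC50+I)`; `I` is the
unbound perpetrator plasma concentration, applied identically at the
hepatic and gut-wall CYP3A4 sites. Structural guarantees tested: a null
perpetrator leaves all fold changes at 1; enzyme levels can never go
negative and the induction asymptote is baseline × (1+Emax); AUC ratios
are monotone in kinact and Emax; enzymes return to baseline after a
washout of ≥ 10/kdeg; and a complete hepatic-CYP3A4 knockout reproduces
the closed-form `AUCR = 1/(1−fm_hep,3A4)` (fm as a fraction of eliminated
drug) to well within 2%.

Perpetrator kinetics are deliberately simple: a one-compartment oral model
read from a config file (bundled clarithromycin and rifampicin files cite
the literature sources of KI/kinact and Emax/EC50 in their headers), or a
user-supplied unbound concentration–time forcing table. The forcing route
runs on the reference R right-hand side. With these simplified
perpetrators the steady-state fold changes for tegoprazan come out near
×3.1 (clarithromycin 500 mg TID) and ÷5.0 (rifampicin 600 mg QD) —
directionally and in magnitude comparable to, but smaller than, the values
obtained with full whole-body perpetrator models, mostly because the
simplified models understate gut-wall perpetrator exposure. The victim-side
mechanism, which is what this package contributes, is unaffected.
`simulate_ddi()` runs the alone and combined arms on identical individuals
after a perpetrator run-in (default 72 h, configurable) and reports each
PK parameter as value plus min–max across the population.

## Evaluation metrics and NCA

`mrd()` is `10^sqrt(mean((log10 Cpred − log10 Cobs)²))`, `gmfe()` is
`10^mean(|log10 PKpred − log10 PKobs|)`, and `twofold_fraction()` counts
`pred/obs ∈ [0.5, 2]` with an inclusive boundary. Pairs with a
non-positive member (below-LLOQ placeholders) are excluded and counted —
neither rule is stated upstream, so both are documented package choices.
NCA uses the linear-up/log-down trapezoid; λz comes from the last 3–10
post-peak points with the best adjusted R², and a non-estimable terminal
phase yields `AUC_inf = NA` with a reason flag. Reproducing the published
MRD/GMFE/two-fold values would require the digitized concentration data of
19 external clinical studies, which are not deposited; the metrics are
instead validated on hand-computed cases, structural properties (symmetry,
the Jensen inequality GMFE ≤ MRD, rescaling invariance) and synthetic
data.

## Parameter identification and identifiability

`fit()` minimises summed squared log10 residuals jointly across datasets —
the geometry of the MRD metric — using Levenberg–Marquardt on
log10-transformed parameters (`minpack.lm`). A damped least-squares search
was chosen over a derivative-free simplex because the CLint problem is
heavily ill-conditioned (see below) and LM is both cheaper per iteration
and better behaved in narrow valleys; the objective and determinism are
unchanged. Datasets flagged `excluded_from_fit` (the metabolite arm of a
DDI-layout study) are dropped, mirroring the exclusion applied during
model development.

The four-way CLint split deserves honesty: parent concentrations identify
the per-enzyme clint sums, metabolite concentrations identify total M1
formation, and the only signal separating CYP3A4→M1 from CYP2C19→M1 is the
small gut-wall CYP3A4 first-pass term. The likelihood surface therefore
has a near-flat valley along which the split trades off. Recovery
exercises in the test suite are run as self-consistency studies around the
generating values: noise-free data return the truth to machine precision,
and at 20% proportional residual error (12 subjects, three dose levels)
all five fitted parameters stay within a few percent of truth. Fits
launched from the in-vitro-derived (ISEF-corrected) starting values
converge on the identifiable combinations but can stall inside the valley
on the split itself — which is precisely why the split entries are seeded
from in-vitro data rather than estimated freely in the original workflow.

`local_sensitivity()` computes normalised central-difference coefficients
`(ΔAUC/AUC)/(Δp/p)` of parent or metabolite AUC. Under perfusion-limited
distribution `AUC_inf` is structurally independent of the partition
coefficients, so lipophilicity has a ~zero coefficient here even though a
permeability-limited implementation ranks it as sensitive; the tests
therefore assert the ranking of the clearance and binding parameters (fu,
CYP3A4→other, CYP2C19→other, renal clearance, in that order of magnitude)
and the vanishing of disconnected parameters, not the lipophilicity rank.

## Synthetic data

`generate_study()` emulates the kind of digitized clinical corpus the
model is developed against: per-subject whole-body simulations
(physiology sampled log-normally; default abundance CV 30%),
multiplicative log-normal residual error (default CV 20% — a stand-in, as
no residual model is reported for digitized data), arithmetic study-mean
profiles, and LLOQ censoring (default 1 ng/mL) with counted records.
`emulate_training_suite()` builds 19 studies spanning 50–400 mg, single
and repeated dosing, fasted and fed arms, split 10 training / 9 test, with
one training arm following a DDI layout whose metabolite dataset is
flagged for exclusion. Everything is a pure function of its seed (the
package's default seed is 20230104), and the generator restores the
caller's RNG state. What the generator does *not* emulate — and therefore
what green tests cannot vouch for on real data — includes the repeated-dose
Cmax decline caused by the drug's own gastric-pH feedback, between-study
demographic heterogeneity, and digitization error structure.

## Numerics

Stiff integration via `deSolve::lsoda`, default rtol 1e-8 / atol 1e-10
µmol, with dose and meal times handled as solver events (integration
restarts at events; the t = 0 output row precedes a t = 0 dose event).
The compiled C right-hand side is the default; a pure-R reference
implementation of the same equations is kept, cross-checked against the C
version in the tests (agreement ~1e-9 relative), and used automatically
for perpetrator forcing tables. Mass conservation holds to <0.1% of dose
at all output times with the parent-side accounting
(lumen + unabsorbed + organs + parent-leaving cumulatives; the →M1
cumulatives track material that lives on in the metabolite states).
Steady state is declared when successive interval AUCs change by <1%;
with a terminal half-life of ~5 h this occurs by day 3 of once-daily
dosing, and simulated horizons are 168 h for terminal mass balances
(>30 half-lives), 7–8 days for steady-state quantities, and 400–700 h for
knockout and washout checks. Fits in the test suite use rtol 1e-6 during
the search; reported simulations use the strict defaults.

## Known limitations

* Gastric-pH feedback of the drug's own pharmacodynamics on later doses is
  not modelled (so repeated-dose Cmax is overpredicted by design).
* CYP3A4-mediated elimination of M1 is not modelled; M1 exposure under
  CYP3A4 perpetrators is therefore not simulated.
* Perpetrators are simplified one-compartment models; printed DDI fold
  changes obtained with full perpetrator models are matched in direction
  and rough magnitude only.
* Blood:plasma partitioning is fixed at 1; saturable metabolism,
  transporters, biliary excretion and enterohepatic recirculation are
  absent (none are part of the source model).
* The specific organ permeability entry is carried in the configs but
  inert under perfusion-limited distribution.
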