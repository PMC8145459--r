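---
title: "Methods: a virtual Chinese paediatric population for PBPK simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a virtual Chinese paediatric population for PBPK simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedpbpk)
```

# What the package models

`pedpbpk` builds virtual Chinese paediatric subjects aged 0–18 years from
published sex-specific growth equations and couples them to physiologically
based pharmacokinetic (PBPK) drug models so that literature trial designs
can be replayed *in silico*. Four intravenous probe drugs are shipped, one
per elimination pathway of interest: theophylline (CYP1A2), fentanyl
(CYP3A4), and ceftazidime and vancomycin (glomerular filtration).
Predictions are judged the way paediatric population models are
conventionally verified: a predicted-to-observed ratio of each PK parameter
inside the inclusive 2-fold band [0.5, 2].

# The population model

## Deterministic backbone

Height for age is a sex-specific polynomial (degree 7 for males, degree 8
for females) evaluated at full coefficient precision; weight combines a
saturating age term with an exponential height–age term, e.g. for males

$$WT = 4.665\,(1 - e^{-1.661\,a}) + e^{0.025\,HT - 0.015\,a}.$$

The printed typography of the weight equations is ambiguous about the
exponent grouping; the combined exponent above is adopted because the
additive alternative yields ≈78 kg at age 18 against an observed mean of
59.4 kg, while the combined reading gives ≈61 kg. Body surface area uses
Haycock below 15 kg and Du Bois at or above 15 kg (the printed boundary
wording is "equal to or greater"). The two formulas agree to 0.1% near
100 cm; at the extremes of the overlap region (90 or 110 cm at exactly
15 kg) the branch jump reaches ≈3.6%, which is a property of the published
coefficients and is asserted as such in the tests.

Cardiac output is $BSA \times [197.444 + 126.667(e^{-0.06a} -
e^{-0.774a})]$ L/h for both sexes; per unit BSA it peaks at age ≈3.58 y and
decays toward 197.4 L/h/m². Six organs (brain, heart, kidney, liver,
pancreas, spleen) follow sex-specific recalibrated equations; printed
denominators 1.04/1.05/1.06 are tissue densities converting mass to
volume. All other tissues (lung, adipose, muscle, skin, bone, gut, blood)
come from a packaged age-indexed fraction-of-body-weight table in the style
of ICRP-89 reference anatomy, linearly interpolated in age, with a residual
rest-of-body tissue closing the whole-body mass balance. The table is the
package's documented stand-in for simulator-internal defaults that are not
public; its rows were fixed once from reference-anatomy values and are not
tuning knobs.

Perfusion splits cardiac output by an age-indexed fraction table; liver
flow is hepatic artery plus the portal organs (gut, spleen, pancreas,
≈25.5% of cardiac output in adults), and a residual fraction closes venous
return to cardiac output exactly.

## Inter-individual variability

Sampling is hierarchical: age uniform within the requested band, sex
Bernoulli, then height = mean curve × mean-preserving lognormal
(CV 6%), weight = weight-given-height curve × lognormal (CV 18%), each
truncated at ±2.5 SD with resampling. Organ volumes receive lognormal
noise (CV 20%; the bulk tissues use half that CV so the mass balance can
close without frequent rejection — draws leaving under 2% of body weight
for the rest compartment are redrawn). The CVs were calibrated once to the
observed SD/mean ratios of the national anthropometry survey (height SD/mean
≈6%, weight ≈26% of which ≈18% is residual after the height term). With
these defaults a 2000-subject male cohort aged 11–12 reproduces the
observed band means (147.67 cm, 40.60 kg) within about 1% and places ≥95%
of simulated heights inside the observed 2.5th–97.5th percentile band.

Haematocrit and albumin are sampled from the observed band statistics
(ages ≥11, truncated to the printed percentile bands); below 11 years the
survey offers no granularity and constants (0.38, 44 g/L) are used. The
survey's "<11 years" column has a mean height of 138.7 cm, which
corresponds to roughly age 10, so the demographic report compares it
against simulated ages 9–11. Serum creatinine is tabulated but plays no
role in the model and is not sampled.

## Renal maturation

GFR uses a sigmoid Hill function of postmenstrual age,
$\mathrm{mat}(PMA) = PMA^{3.4}/(PMA^{3.4} + 47.7^{3.4})$ with PMA in weeks
(term birth = 40 weeks), scaled by $BSA/1.73$ and an adult reference of
121 mL/min — the standard published maturation model, adopted because no
Chinese paediatric GFR data were available to the population model. Only
term subjects are modelled; preterm neonates are out of scope.

# IVIVE and clearance

Hepatic clearance scales per-pmol in vitro intrinsic clearances through
ontogeny-adjusted enzyme abundances (adult values 52/8/61/137 pmol/mg for
CYP1A2/2D6/2E1/3A4), microsomal protein per gram of liver
($10^{1.407+0.0158a-0.000384a^2+3.3\times10^{-6}a^3}$ mg/g, ≈26 at birth
to ≈42 in adults), and the liver mass from the population equations, then
through the well-stirred model
$CL_h = Q_h f_{u,b} CL_{int,u}/(Q_h + f_{u,b} CL_{int,u})$ (blood
clearance, converted to plasma reference by the blood:plasma ratio). Renal
clearance scales the adult $CL_R$ by the subject's GFR fraction of
121 mL/min; ceftazidime and vancomycin carry no enzyme kinetics, so their
systemic clearance is the GFR-scaled $CL_R$ alone. A drug-level
`clint_calibration` factor (default 1) anchors the adult reference
clearance to an external in vivo value.

## Choice of ontogeny profiles and calibration factors

Two system-level choices deserve explanation because they are the main
degrees of freedom the published sources leave open.

*Ontogeny.* In-vitro protein-abundance ontogeny curves for CYP1A2 put
essentially no activity at birth, yet the observed neonatal clearance of
theophylline — the package's CYP1A2 probe — is only ≈40% below the adult
per-kg value. Commercial paediatric simulators resolve this by using
in-vivo-derived ontogeny functions (built from caffeine/theophylline data
for CYP1A2 and midazolam data for CYP3A4), and this package does the same:
the shipped Hill profiles (CYP1A2 $f_{birth}$ 0.28, age50 0.60 y, n 1.2;
CYP3A4 0.25/0.30 y/1.0; CYP2D6 0.10/0.10/1.0; CYP2E1 0.10/0.50/1.0)
represent apparent in vivo maturation. They are system inputs in the
packaged YAML (`cn_pediatric_system.yaml`), not claims about protein
expression, and can be replaced wholesale via `read_system_file()`.

*Adult anchoring.* With the liver sizes produced by the population
equations (≈1.27 L for the 70 kg reference male) the raw IVIVE chain gives
an adult theophylline plasma clearance of ≈2.4 L/h and fentanyl ≈34 L/h,
somewhat below accepted adult values. The shipped models therefore carry
calibration factors of 1.25 (theophylline) and 1.60 (fentanyl) that anchor
the adult reference clearance to ≈2.9 L/h (0.70 mL/min/kg) and ≈44 L/h
(0.63 L/h/kg) respectively — both mid-range adult literature values. This
mirrors the usual PBPK practice of verifying a compound file in adults
before applying it to children; the factors are visible fields of the drug
JSON, not hidden constants.

# Disposition models

Theophylline uses a minimal (one-compartment) disposition model with
volume $V_{ss} \times WT$ and the mechanistic total clearance. No satellite
compartment is modelled because no parameters for one are available; the
practical consequence is a slightly lower early Cmax than a minimal-plus-
satellite implementation would give, which is why neonatal Cmax agreement
is expected to be approximate.

The other three drugs use a full perfusion-rate-limited model: venous and
arterial blood, lung in series, and twelve tissues with
$V_t\,dC_t/dt = Q_t(C_{art} - C_t/(K_{p,t}/BP))$. The liver receives
hepatic-arterial plus portal inflow and eliminates on its outflow blood at
$f_{u,b} CL_{int,u}$ (well-stirred equivalence); renal clearance acts on
venous plasma. The renal site is a deliberate deviation from a literal
filtration-at-the-glomerulus formulation: applying $CL_R$ at the arterial
node makes the plasma clearance recovered from venous sampling equal
$CL_R \cdot CO/(CO + CL_R/BP)$ rather than $CL_R$, and the reported renal
clearances being venous-plasma quantities, the venous formulation is the
faithful one (the difference is ≈3% for ceftazidime).

Tissue:plasma partition coefficients come from Rodgers–Rowland-style
composition equations (tissue water, neutral lipid/phospholipid, acidic
phospholipid binding for moderate-to-strong bases back-calculated from the
blood:plasma ratio, albumin-type binding for acids back-calculated from
$f_u$). Because the exact tissue-composition tables of the reference
implementation are not public, every Kp set is calibrated by a single
scalar so that the adult reference subject's plasma-referenced
$V_{ss} = BP \cdot V_{blood} + \lambda \sum_t K_{p,t} V_t$ equals the
compound's reported value (4.071, 0.195 and 0.445 L/kg for fentanyl,
ceftazidime, vancomycin). This anchoring makes the composition details
second-order for the simulated kinetics.

## Numerics

The disposition systems are linear, so integration proceeds segment by
segment between dose boundaries with `deSolve::lsoda`, a constant analytic
Jacobian, rtol 1e-8 and atol 1e-10 mg; boluses are state jumps, infusions
piecewise-constant inputs, and requested output times are honoured exactly.
Elimination accumulates in explicit mass-balance compartments, and the
invariant (body + eliminated = administered, within 0.1% at every output
time; in practice ~1e-15) is asserted in the tests. Results are invariant
to tolerance halving within 0.05%.

NCA uses the standard linear-up/log-down trapezoid (a plain linear option
exists), $\lambda_z$ from a log-linear fit of the terminal 3–4 points, and
$CL = \text{dose}/AUC_{0-\infty}$ for single doses or daily dose over the
final-24-h AUC at steady state for multiple dosing. On the packaged
sampling grids the NCA clearance matches the mechanistic clearance within
0.5% for the minimal model and ≈2% for the full models.

# Trial replication

Each packaged study design records the literature dose, age band and
(where unprinted, the package's documented choices) infusion duration and
sampling grid: theophylline 30-min infusions sampled to 72 h in neonates
(long half-life) and 48 h in children; fentanyl bolus sampled to 12 h;
ceftazidime 30-min infusion to 12 h; vancomycin daily dose split q12h as
60-min infusions for 5 days with AUC over the final 24 h. Cohorts default
to 10 replicate trials of 10 subjects; summaries pool all subjects
(arithmetic mean ± SD), matching the single mean±SD presentation of the
source verification tables. A master seed spawns per-study seeds
deterministically, so every report is byte-reproducible.

For micro-dosed fentanyl the concentration scale is ng/mL; note that a
bolus Cmax in a whole-body model is the concentration in venous blood at
the first sampling time and is therefore sampling-grid-dependent — Cmax is
reported but only clearance and AUC are used for evaluation of the
renally- and metabolically-cleared endpoints.

# What the synthetic cohorts do and do not show

The generator emulates the anthropometry, organ growth, perfusion, enzyme
maturation and renal maturation of healthy term Chinese children, with
independent lognormal organ variability. It does not emulate: correlated
organ co-variation beyond the shared body-size axis, disease states,
preterm physiology, circadian or food effects, transporter ontogeny, or
plasma-protein ontogeny beyond the binary neonatal fraction-unbound
override for theophylline. Passing the packaged verifications therefore
shows that the implemented equations and scaling rules reproduce the
reference behaviour under these idealised conditions, not that the model
is validated for clinical dosing decisions.

# Problem sizes and determinism

The shipped verification surface uses 10×10-subject trial replicates per
study, 2000–4000-subject demographic cohorts, and fixed seeds throughout;
these sizes give Monte-Carlo standard errors of ≈1–3% on pooled means,
small against the 2-fold evaluation band. All randomness flows through R's
RNG from user-supplied seeds; identical seeds give bit-identical outputs.

# Known limitations

* Simulator-internal reference data (tissue compositions, exact ontogeny
  and MPPGL curves, minimal-model satellite parameters) are not public, so
  quantitative agreement with the reference implementation is approximate
  by construction; the package's own acceptance band is the 2-fold
  criterion.
* Childhood CYP1A2 activity per kg of body weight is known to exceed the
  adult value in vivo; the ontogeny profiles are capped at 1, so the
  package under-predicts mid-childhood theophylline clearance (ratio ≈0.6
  against the reference prediction, still within the band).
* The under-11 haematocrit/albumin constants flatten true age trends
  (neonatal haematocrit in particular); these quantities do not feed the
  clearance chain.
* Observed literature values pooled from small paediatric studies are
  internally inconsistent in places (e.g. a vancomycin study whose
  observed CL and AUC do not satisfy AUC = dose/CL); ratios are reported
  against the values as published.
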