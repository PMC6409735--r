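---
title: "A cell-level systems PK-PD model for antibody-drug conjugates"
author: "adcpkpd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A cell-level systems PK-PD model for antibody-drug conjugates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adcpkpd)
```

## The problem

Antibody-drug conjugates (ADCs) couple a targeting antibody to a cytotoxic
payload through a cleavable linker.  Their efficacy against solid tumors is
driven not by plasma exposure but by how much payload reaches, enters and
is retained inside tumor cells.  `adcpkpd` implements a multiscale model of
this chain for trastuzumab-vc-MMAE (an anti-HER2 IgG1 carrying monomethyl
auristatin E, average drug-to-antibody ratio DAR ~4) in two xenograft
settings: a HER2-high gastric carcinoma (N87, in-vivo antigen estimate
185,000 receptors/cell) and a HER2-low breast carcinoma (GFP-MCF7, 22,400
receptors/cell).  The package provides the coupled simulator, a synthetic
study generator matching the designs such models are calibrated on, and a
staged maximum-likelihood estimator whose purpose is parameter recovery:
simulate at known values, add realistic noise, refit, and quantify how well
each stage identifies its parameters.

## Model structure

The state vector has fifteen components in four blocks, all integrated
jointly (compiled right-hand side in `src/adc_model.c`; a readable R
composition `adc_rhs_r()` backs the consistency tests).

**Plasma.** Conjugate amounts $X_1, X_2$ (nmol) follow a linear
two-compartment model with central clearance $CL_{ADC}$ and an additional
first-order deconjugation loss $K_{dec}$; the average DAR declines as
$\bar{D}(t) = \bar{D}_0 e^{-K_{dec} t}$.  Free payload concentrations
$C_1, C_2$ (nM) follow their own two-compartment model; both the catabolic
and deconjugation routes of the conjugate form payload in proportion to the
current $\bar{D}$.

**Tumor distribution.** A well-mixed Krogh-cylinder description: exchange
between the plasma and the tumor extracellular space proceeds at
$k_{ex} = 2PR_{cap}/R_{Krogh}^2 + 6D/R_{tumor}^2$ per day — a vascular
permeability term and a surface diffusion term, the latter fading as the
tumor radius grows.  Only the void fraction $\varepsilon$ of the tumor is
accessible, so the free interstitial concentration is the tumor-average
concentration divided by $\varepsilon$.  The conjugate state is carried as
nM per total tumor volume, the payload state as an amount (nmol).

**Single cell.** One average cell, scaled by the cell number
$N_C = 10^5 \cdot TV_{mm^3}$ (i.e. $10^8$ cells/g at unit density), carries
four molecule-count states: antigen-bound conjugate (capacity $Ag_{ex}$,
binding on the free interstitial concentration), endosomal/lysosomal
conjugate after internalization ($K_{int}$), free cytoplasmic payload
released by lysosomal degradation ($K_{deg}$, $\bar{D}$ molecules per
conjugate), and tubulin-bound payload.  Payload exchanges with the
extracellular space by first-order influx/efflux ($K_{in}/K_{out}$; their
ratio makes the intracellular free concentration ~180-fold the
interstitial one at steady state, the saturable retention mechanism) and
binds tubulin (65 nM intracellular capacity) by mass action.  All per-cell
species are diluted at the tumor growth rate $0.693/DT$ so that the total
cell-associated amount is invariant under growth alone.  The
pharmacodynamic driver is percent tubulin occupancy
$Occ = 100 \cdot Drug_{b}/Tub_{tot}$.

**Growth inhibition.** Growing volume $TV_1$ expands at $K_g = 0.693/DT$
and is shuttled by a Hill kill function
$Kill = K_{max} Occ^{\gamma} / (KC_{50}^{\gamma} + Occ^{\gamma})$ through
three non-growing transit compartments with time constant $\tau$; cells
exiting the last compartment die and (in the PD-coupled mode) release
their intracellular content back into the extracellular space.  With the
steep estimated Hill coefficient ($\gamma \approx 15$) the kill acts as a
near-threshold switch around $KC_{50} \approx 97\%$ occupancy — killing
requires nearly saturated tubulin.

## Units and implicit constants

Internally everything runs in days, litres, nanomoles, nM, molecules/cell
and mm^3.  Cell-level rates are tabulated per hour and converted once at
load (`adc_params()`); a unit audit test asserts the conversion.  The
molecules-to-nanomoles bridge is $SF = 10^9/N_A$.  Four constants the
parameterization needs but does not state are surfaced as overridable
assumptions with these defaults: conjugate molar mass 150,000 g/mol (IgG1
plus ~4 linkers), body weight 0.02 kg, single-cell volume 1 pL (typical
carcinoma cell; it sets both the tubulin copy number, ~39,000/cell, and
the cellular volume fraction, ~10%), and 10^5 cells/mm^3.

## Estimation

Calibration is sequential, mirroring how such models are developed:

1. **Plasma stage** frees $\{CL_{ADC}, CLD_{ADC}, V_{1,ADC}, V_{2,ADC},
   K_{dec}\}$ against the three plasma analytes (total antibody,
   unconjugated payload, total payload) pooled over both tumor models.
   Predictions use the full tumor-bearing system with the tumor and cell
   blocks frozen at their literature values: at a 500 mm^3 tumor the
   plasma-to-tumor drain is a non-negligible clearance route, and fitting
   a plasma-only model to tumor-bearing data would bias the central
   clearance upward by ~50% (measured on noiseless data).
2. **Tumor stage** frees only the per-model antigen count $Ag_{ex}$
   against the tumor analytes, plasma frozen.
3. **PD stage** frees $\{K_{max}, KC_{50}, \tau\}$ against tumor-volume
   curves from all arms of both models, with $\gamma$ and the doubling
   times fixed (the doubling times are recovered separately from the
   control arms by an exponential fit, `fit_growth()`).

The residual model is the combined-error variance
$Var(t) = (\sigma_{int} + \sigma_{slope} Y(t))^2$ evaluated at the model
prediction.  With a purely proportional error ($\sigma_{int}=0$) the
per-stream maximum-likelihood $\hat\sigma_{slope}$ has a closed form and is
profiled out analytically, so no variance parameters enter the numerical
search; fixed $(\sigma_{int}, \sigma_{slope})$ pairs are supported as an
option.  Optimization is Nelder-Mead on log-transformed parameters (Brent
for the one-dimensional antigen fit), with optional jittered multi-starts
(default 5 for the plasma stage).  Precision (CV%) comes from the inverse
finite-difference Hessian of the objective at the optimum; it is a
plug-in approximation conditional on the profiled sigmas.  $\gamma$ is
deliberately not freed by default: with a switch-like Hill it is weakly
identifiable, and recovery claims for it would be order-of-magnitude at
best.

## The synthetic study generator

`generate_pk_dataset()` emulates a destructive tumor PK study: every
animal gives an early (10 min) plasma sample; at 1, 3 and 7 days, three
animals per group are sacrificed for paired terminal plasma and tumor
samples, each assayed for the three analytes.  `generate_tgi_dataset()`
emulates dose-ranging efficacy arms (vehicle plus 1-10 mg/kg, n = 7,
twice-weekly calliper measurements realized as days 0, 3, 7, 10, ... out
to 48 days, administrative censoring above 2000 mm^3).  Noise is additive
Gaussian with SD $= \sigma_{int} + \sigma_{slope} Y$, truncated at zero —
the same structure the estimator assumes.  Subject-level log-normal
variability on $K_{max}$ (10.16% CV) and $\tau$ (19.4% CV) can be applied
in simulation; population estimation of those variabilities is out of
scope, so recovery experiments use zero-IIV data and pooled fixed-effects
ML.  The generator does not emulate assay quantification limits, PK-level
inter-animal variability, or measurement-error correlation within an
animal; passing recovery therefore demonstrates identifiability and
estimator correctness under the stated noise model, not robustness to
every feature of real bioanalytical data.

## Numerical choices

- `lsoda` with `rtol = 1e-8` and per-state absolute tolerances scaled to
  typical magnitudes; the steep Hill term and the fast payload influx make
  the PD-coupled system stiff.  Recovery fits use `rtol = 1e-6` — a grid
  refinement test shows terminal observables move by < 0.1% when
  tolerances are tightened 100-fold.
- Stiff steps can transiently undershoot zero; states are clipped to zero
  within a small relative band and anything beyond it is an error.
- The growth rate uses the conventional rounded constant $0.693/DT$, so a
  "doubling" takes $DT \ln 2 / 0.693 \approx 1.0002\,DT$; tests use
  tolerances wide enough not to care.
- Payload mass bookkeeping in the printed equation set has two deliberate
  asymmetries that the conservation tests must respect.  First,
  deconjugation decrements both the conjugate amount and the average DAR
  while re-injecting payload only once, so total payload is not conserved
  when $K_{dec} > 0$ even with all clearances off.  Second, the tumor
  conjugate state is a concentration without a growth-dilution term, so a
  growing tumor volume manufactures conjugate amount.  The closed-system
  audit therefore sets $K_{dec} = 0$ and freezes growth, while keeping
  $CL_{ADC} > 0$ to exercise the catabolism-to-payload route; under those
  conditions total payload is conserved to ~1e-10.
- Peripheral-compartment conjugate never re-injects payload; the
  conservation test also zeroes $CLD_{ADC}$.

## Recovery experiment sizes

The validation suite and `scripts/acceptance.R` use ten independent study
replicates per experiment, proportional noise $\sigma_{slope} = 0.05$, and
three animals per TGI arm.  Three animals per arm is an information-free
scale-down at zero IIV (all subjects share the arm's typical curve), and
keeps a full eight-arm PD refit to a few seconds.  Medians across seeds
are compared with the generating values: the plasma stage recovers
$K_{dec}$ and $CL_{ADC}$ to well under 10%, the antigen counts recover to
~1%, the kill parameters to ~1%, and the doubling times to under 1%.

## Known limitations

- The fitted-parameter set implies a tumor free-conjugate pool near
  $\varepsilon_{ADC} \cdot C_{plasma}$ (the Krogh exchange equilibrates
  within hours and nothing drains the pool faster than it refills).
  Homogenate total-antibody concentrations are therefore dominated by this
  antigen-independent term, and the model-implied high/low-antigen
  fold-difference in tumor antibody AUC(0-7 d) is only ~1.3, with the
  unconjugated-payload fold at ~3.1 and total payload at ~1.9.  In-vivo
  studies of this ADC pair report a much larger antibody differential
  (order 10-fold) and a smaller unconjugated-payload one (~1.6-fold); the
  printed equation structure at the tabulated parameter values cannot
  reproduce the former, which the acceptance report states as computed
  rather than masking.  Total payload is the analyte this structure gets
  right.
- One average cell represents all tumor cells, shared across growing and
  dying subpopulations; there is no bystander or multi-population
  extension, no resistant fraction, and no immune compartment.
- No target-mediated disposition in plasma, no lymphatic convection, no
  FcRn recycling, no DAR-species-resolved binding (average-DAR
  bookkeeping), and no allometric scaling beyond the mouse.

## A worked simulation

```{r example, eval = FALSE}
p <- adc_params("n87")
sim <- simulate_adc(p, dose = 10, times = seq(0, 21, 0.1), mode = "pkpd")
head(sim_observables(sim))
tv <- rowSums(sim$states[, c("TV1", "TV2", "TV3", "TV4")])
time_to_volume(sim$times, tv, 1000)
```
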