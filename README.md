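# adcpkpd

A cell-level systems pharmacokinetic-pharmacodynamic (PK-PD) model for
antibody-drug conjugates (ADCs), with trastuzumab-vc-MMAE in HER2-high
(N87) and HER2-low (GFP-MCF7) xenografts as the worked case.

ADC efficacy against solid tumors is governed by what happens after the
plasma: penetration into the tumor, receptor-mediated uptake into cells,
lysosomal payload release, and retention on the intracellular target.
`adcpkpd` is for modelers who want to simulate and calibrate that whole
chain rather than an empirical exposure-response curve. It couples:

- **Plasma PK** — linear two-compartment disposition of the conjugate
  (amounts X1, X2) and the free payload (concentrations C1, C2), with
  non-specific deconjugation `Kdec_P` driving a first-order decline of the
  average drug-to-antibody ratio, `DAR(t) = DAR0·exp(-Kdec_P·t)`; both
  catabolism and deconjugation form free payload.
- **Krogh-cylinder tumor distribution** — plasma/tumor exchange at
  `2·P·R_cap/R_Krogh² + 6·D/R_tumor²` per day (vascular + surface terms),
  with void fractions ε converting tumor-average to interstitial
  concentrations.
- **Single-cell disposition** — antigen binding (capacity `Ag_ex`
  receptors/cell), internalization, lysosomal degradation releasing DAR
  payload molecules, payload influx/efflux, mass-action binding to
  intracellular tubulin, and growth dilution at `0.693/DT`. The PD driver
  is percent tubulin occupancy, `Occ = 100·Drug_b/Tub_tot`.
- **Tumor growth inhibition** — a Hill kill function
  `Kill = Kmax·Occ^γ/(KC50^γ + Occ^γ)` (γ ≈ 15: a near-threshold switch
  around KC50 ≈ 97% occupancy) shuttling growing volume through three
  transit compartments (time constant τ), with dying cells releasing
  their contents back to the extracellular space.

On top of the simulator the package provides non-compartmental summaries
(trapezoidal AUC, terminal half-life, exposure ratios), a synthetic
xenograft study generator (destructive PK sampling, twice-weekly tumor
volumes, combined-error residual noise, log-normal inter-individual
variability on `Kmax` and τ), and staged maximum-likelihood estimation
(plasma → antigen → kill parameters) with parameter-recovery tooling.

## Worked example

```r
library(adcpkpd)
p <- adc_params("n87")                       # bundled parameter set, HER2-high
sim <- simulate_adc(p, dose = 10, times = c(10/1440, 1, 3, 7), mode = "pk")
sim_observables(sim, long = FALSE)[, c(1, 2, 4, 6, 9)]
#>   time plasma.total_trastuzumab plasma.total_mmae tumor.total_trastuzumab tumor.tubulin_occupancy
#> 1 0.01                   793.65           3174.60                    0.00                    0.00
#> 2 1.00                   259.50            756.01                   93.20                   98.63
#> 3 3.00                    81.00            123.92                   43.05                   98.50
#> 4 7.00                     8.19              3.48                    5.88                   89.91
```

At 10 mg/kg the initial plasma antibody concentration is 793.65 nM
(66.7 nmol/kg at 150 kDa in an 84 mL/kg central volume) and total MMAE
starts 4-fold higher, reflecting the initial DAR of 4. Tubulin occupancy
in the high-antigen tumor saturates near 99% within a day and is still
~90% at day 7 — long after plasma has declined — which is why occupancy,
not plasma concentration, drives the kill model.

```r
terminal_half_life(sim_curve(sim, "plasma", "total_trastuzumab"))
#> [1] 1.2        # days; total MMAE ~0.77 d, unconjugated MMAE ~1.06 d

spd <- simulate_adc(p, dose = 3, times = seq(0, 48, 0.25), mode = "pkpd")
tv <- rowSums(spd$states[, c("TV1", "TV2", "TV3", "TV4")])
time_to_volume(spd$times, tv, 1000)
#> [1] Inf        # 3 mg/kg holds the high-antigen tumor below 1000 mm^3
```

A fitting round-trip — generate a noisy synthetic study at the bundled
values, then refit one stage:

```r
obs <- generate_pk_dataset(pk_design("n87", sigma_slope = 0.05, seed = 7), p)
fit_stage("tumor", obs, p)    # refits Ag_ex; recovers ~185,000 within a few %
```

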