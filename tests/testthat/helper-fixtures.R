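# Shared fixtures: canonical parameter sets and small simulation helpers.

p_n87 <- adc_params("n87")
p_mcf7 <- adc_params("mcf7")

# total payload (MMAE) in nmol summed over plasma, tumor extracellular and
# cell-associated pools, conjugated plus unconjugated
total_mmae_nmol <- function(sim) {
  p <- sim$params
  st <- sim$states
  bw <- p$body_weight
  TVmm3 <- rowSums(st[, c("TV1", "TV2", "TV3", "TV4")])
  TV_L <- TVmm3 * 1e-6
  NC <- TVmm3 * p$cells_per_mm3
  st[, "DAR"] * (st[, "X1_ADC"] + st[, "X2_ADC"] +
                   st[, "ADCf_ex"] * TV_L +
                   (st[, "ADCb_cell"] + st[, "ADClyso_cell"]) * NC * SF) +
    st[, "C1_Drug"] * p$V1_Drug * bw + st[, "C2_Drug"] * p$V2_Drug * bw +
    st[, "Drugf_ex"] +
    (st[, "Drugf_cell"] + st[, "Drugb_cell"]) * NC * SF
}

tv_total <- function(sim) rowSums(sim$states[, c("TV1", "TV2", "TV3", "TV4")])
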