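test_that("cell RHS vanishes at the empty state", {
  cells <- c(ADCb_cell = 0, ADClyso_cell = 0, Drugf_cell = 0, Drugb_cell = 0)
  d <- cell_rhs(cells, ADCf_ex = 0, Drugf_ex = 0, TV_mm3 = 500, p = p_n87,
                DAR = 4)
  expect_equal(unname(d), rep(0, 4))
})

test_that("receptor binding equilibrates at the analytic oracle", {
  # Kd = Koff/Kon = 0.014/0.03 = 0.4667 nM
  Kd <- p_n87$Koff_ADC / p_n87$Kon_ADC
  expect_equal(Kd, 0.4667, tolerance = 1e-3)
  expect_equal(cell_equilibrium_bound(Kd, 185000, p_n87$Kon_ADC,
                                      p_n87$Koff_ADC),
               92500, tolerance = 1e-6)
  expect_equal(cell_equilibrium_bound(1e9, 185000, 1, 1), 185000,
               tolerance = 1e-6)

  # integrate the binding subsystem at constant interstitial concentration
  # (internalization, deconjugation and dilution off) to steady state
  p <- adc_params("n87", Kint_ADC = 1e-12, Kdec_P = 0, DT = 1e12)
  C_int <- 2.5  # nM free interstitial
  rhs <- function(t, y, parms) {
    list(cell_rhs(y, ADCf_ex = C_int * p$eps_ADC, Drugf_ex = 0,
                  TV_mm3 = 500, p = p, DAR = 0))
  }
  y0 <- c(ADCb_cell = 0, ADClyso_cell = 0, Drugf_cell = 0, Drugb_cell = 0)
  out <- deSolve::ode(y0, c(0, 50), rhs, NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-8)
  expect_equal(out[2, "ADCb_cell"],
               cell_equilibrium_bound(C_int, p$Ag_ex, p$Kon_ADC, p$Koff_ADC),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("tubulin occupancy is half-maximal at the payload Kd", {
  Kd_tub <- p_n87$Koff_Tub / p_n87$Kon_Tub
  expect_equal(Kd_tub, 29.78, tolerance = 1e-3)
  # free intracellular payload at Kd (in molecules) and half-bound tubulin:
  # the tubulin-binding flux balances dissociation exactly
  tubm <- tubulin_molecules_per_cell(p_n87$Tub_total, p_n87$V_cell)
  dfc <- Kd_tub * 1e-9 * p_n87$V_cell * AVOGADRO  # molecules at Kd conc
  p <- adc_params("n87", DT = 1e12, Kdeg_ADC = 1e-12, Kout_Drug = 1e-12,
                  Kin_Drug = 1e-12)
  d <- cell_rhs(c(ADCb_cell = 0, ADClyso_cell = 0, Drugf_cell = dfc,
                  Drugb_cell = tubm / 2),
                ADCf_ex = 0, Drugf_ex = 0, TV_mm3 = 500, p = p, DAR = 0)
  expect_equal(d[["Drugb_cell"]], 0, tolerance = 1e-6)
})

test_that("occupancy maps bound payload to percent of tubulin", {
  expect_equal(tubulin_occupancy(0, p_n87), 0)
  tubm <- tubulin_molecules_per_cell(65, 1e-12)
  expect_equal(tubulin_occupancy(tubm / 2, p_n87), 50)
  expect_equal(tubulin_occupancy(37187, p_n87), 95.0, tolerance = 1e-3)
})

test_that("occupancy stays within [0, 100] across random simulations", {
  set.seed(42)
  for (i in 1:6) {
    p <- adc_params(sample(c("n87", "mcf7"), 1),
                    Kon_Tub = 0.0183 * 24 * runif(1, 0.2, 5),
                    Kin_Drug = 8.33 * 24 * runif(1, 0.2, 5),
                    Ag_ex = 10^runif(1, 4, 6))
    sim <- simulate_adc(p, dose = runif(1, 1, 20),
                        times = seq(0, 21, 0.25),
                        mode = sample(c("pk", "pkpd"), 1))
    occ <- sim_curve(sim, "tumor", "tubulin_occupancy")$value
    expect_true(all(occ >= 0 & occ <= 100 + 1e-6))
  }
})

test_that("steady-state retention is saturable (concave in exposure)", {
  # doubling the free concentration less than doubles equilibrium binding
  # once occupancy exceeds 50%
  Kd <- 29.78
  C <- Kd * 1.5  # occupancy 60%
  b1 <- cell_equilibrium_bound(C, 39144, 1, Kd)
  b2 <- cell_equilibrium_bound(2 * C, 39144, 1, Kd)
  expect_gt(b1 / 39144, 0.5)
  expect_lt(b2, 2 * b1)
})

test_that("growth dilution exactly offsets population growth", {
  # no exchange, no processing: per-cell content decays at 0.693/DT while
  # the cell number grows at 0.693/DT, so the total is invariant
  p <- adc_params("n87", Kon_ADC = 1e-12, Koff_ADC = 1e-12,
                  Kint_ADC = 1e-12, Kdeg_ADC = 1e-12, Kon_Tub = 1e-12,
                  Koff_Tub = 1e-12, Kin_Drug = 1e-12, Kout_Drug = 1e-12,
                  Kdec_P = 0)
  sim <- simulate_adc(p, dose = 0, times = seq(0, 14, 0.25), mode = "pk",
                      tv0 = 400,
                      init = c(ADCb_cell = 1000, Drugb_cell = 500),
                      rtol = 1e-10)
  NC <- tv_total(sim) * p$cells_per_mm3
  tot_b <- sim$states[, "ADCb_cell"] * NC
  tot_d <- sim$states[, "Drugb_cell"] * NC
  expect_lt(max(abs(tot_b / tot_b[1] - 1)), 1e-7)
  expect_lt(max(abs(tot_d / tot_d[1] - 1)), 1e-7)
})
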