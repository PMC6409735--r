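test_that("compiled and R reference right-hand sides integrate identically", {
  amt <- dose_to_nmol(10, p_n87$MW_ADC, p_n87$body_weight)$nmol
  y0 <- stats::setNames(numeric(15), adcpkpd:::.state_names)
  y0["DAR"] <- 4; y0["TV1"] <- 375; y0["X1_ADC"] <- amt
  for (mode in c("pk", "pkpd")) {
    flags <- list(p = p_n87, kill = mode == "pkpd",
                  release = mode == "pkpd", tumor = TRUE)
    oR <- deSolve::ode(y0, seq(0, 10, 0.1), adc_rhs_r, parms = flags,
                       method = "lsoda", rtol = 1e-9, atol = 1e-10)
    sC <- simulate_adc(p_n87, 10, times = seq(0, 10, 0.1), mode = mode,
                       tv0 = 375, rtol = 1e-9)
    err <- max(abs(oR[, -1] - sC$states) / (abs(sC$states) + 1e-6))
    expect_lt(err, 1e-5)
  }
})

test_that("solutions are converged with respect to integrator tolerance", {
  tt <- seq(0, 7, 0.1)
  s1 <- simulate_adc(p_n87, 10, times = tt, mode = "pkpd", rtol = 1e-8)
  s2 <- simulate_adc(p_n87, 10, times = tt, mode = "pkpd", rtol = 1e-10)
  o1 <- sim_observables(s1, long = FALSE)
  o2 <- sim_observables(s2, long = FALSE)
  last <- nrow(o1)
  for (col in setdiff(names(o1), "time")) {
    expect_lt(abs(o1[last, col] - o2[last, col]) /
                (abs(o2[last, col]) + 1e-9), 1e-3)
  }
})

test_that("an untreated tumor grows exponentially at 0.693/DT", {
  sim <- simulate_adc(p_mcf7, dose = 0, times = seq(0, 21, 0.5),
                      mode = "pkpd", tv0 = 375)
  expect_equal(tv_total(sim), 375 * exp(growth_rate(10.6) * sim$times),
               tolerance = 1e-6)
  expect_true(all(sim_curve(sim, "tumor", "tubulin_occupancy")$value == 0))
})

test_that("plasma conjugate analytes are dose-linear with the tumor decoupled", {
  p <- adc_params("n87", P_ADC = 0, D_ADC = 0, P_Drug = 0, D_Drug = 0)
  tt <- seq(0, 7, 0.25)
  s1 <- simulate_adc(p, 2, times = tt, mode = "pk")
  s2 <- simulate_adc(p, 8, times = tt, mode = "pk")
  c1 <- sim_curve(s1, "plasma", "total_trastuzumab")$value
  c2 <- sim_curve(s2, "plasma", "total_trastuzumab")$value
  expect_equal(c2, 4 * c1, tolerance = 1e-6)
})

test_that("initial observables reproduce the dosing arithmetic", {
  sim <- simulate_adc(p_n87, 10, times = c(0, 1), mode = "pk")
  obs <- sim_observables(sim, long = FALSE)
  expect_equal(obs$plasma.total_trastuzumab[1], 793.65, tolerance = 1e-4)
  expect_equal(obs$plasma.total_mmae[1], 3174.6, tolerance = 1e-4)
  expect_equal(obs$plasma.dar[1], 4)
  expect_equal(obs$tumor.total_trastuzumab[1], 0)
})

test_that("total payload dominates unconjugated payload everywhere", {
  for (m in c("n87", "mcf7")) {
    sim <- simulate_adc(adc_params(m), 10, times = seq(0, 7, 0.1),
                        mode = "pk")
    obs <- sim_observables(sim, long = FALSE)
    expect_true(all(obs$tumor.total_mmae >=
                      obs$tumor.unconjugated_mmae - 1e-9))
    expect_true(all(obs$plasma.total_mmae >=
                      obs$plasma.unconjugated_mmae - 1e-9))
  }
})

test_that("the high-antigen model sustains higher tubulin occupancy", {
  tt <- seq(0, 7, 0.1)
  occ_hi <- sim_curve(simulate_adc(p_n87, 10, times = tt, mode = "pk"),
                      "tumor", "tubulin_occupancy")$value
  occ_lo <- sim_curve(simulate_adc(p_mcf7, 10, times = tt, mode = "pk"),
                      "tumor", "tubulin_occupancy")$value
  expect_true(all(occ_hi[-1] >= occ_lo[-1] - 1e-6))
  expect_gt(max(occ_hi), 90)  # rises toward a plateau near saturation
})

test_that("simulation inputs are validated", {
  expect_error(simulate_adc(p_n87, -1), "non-negative")
  expect_error(simulate_adc(p_n87, 10, times = c(1, 0.5)), "increasing")
  expect_error(simulate_adc(p_n87, 10, tv0 = 0), "positive")
  expect_error(simulate_adc(p_n87, 10, init = c(bogus = 1)), "unknown state")
})

test_that("repeat dosing adds boluses at event times", {
  tt <- sort(unique(c(seq(0, 14, 0.25), 7.0001)))
  s1 <- simulate_adc(p_n87, 5, times = tt, mode = "pk", tumor = FALSE)
  s2 <- simulate_adc(p_n87, 5, times = tt, mode = "pk", tumor = FALSE,
                     dose_times = c(0, 7))
  x1 <- s1$states[, "X1_ADC"]
  ij <- which(tt == 7.0001)  # just after the second bolus
  amt <- dose_to_nmol(5, p_n87$MW_ADC, p_n87$body_weight)$nmol
  expect_equal(unname(s2$states[ij, "X1_ADC"]), x1[[ij]] + amt,
               tolerance = 1e-3)
  i7 <- which(tt == 7)
  expect_equal(s2$states[1:(i7 - 1), ], s1$states[1:(i7 - 1), ],
               tolerance = 1e-8)
})
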