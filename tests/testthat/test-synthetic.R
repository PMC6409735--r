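test_that("generation is deterministic in (design, params, seed)", {
  d1 <- generate_pk_dataset(pk_design("n87", seed = 7), p_n87)
  d2 <- generate_pk_dataset(pk_design("n87", seed = 7), p_n87)
  d3 <- generate_pk_dataset(pk_design("n87", seed = 8), p_n87)
  expect_identical(d1, d2)
  expect_false(isTRUE(all.equal(d1$value, d3$value)))
  expect_error(pk_design("n87"), "seed")
  expect_error(tgi_design("n87"), "seed")
})

test_that("vanishing noise reproduces the model predictions exactly", {
  des <- pk_design("n87", sigma_slope = 1e-12, seed = 3)
  d <- generate_pk_dataset(des, p_n87)
  sim <- simulate_adc(p_n87, 10,
                      times = sort(unique(c(0, d$time))), mode = "pk",
                      tv0 = 500)
  obs <- sim_observables(sim)
  key <- function(x) paste(x$time, x$matrix, x$analyte)
  pred <- obs$value[match(key(d), key(obs))]
  expect_equal(d$value, pred, tolerance = 1e-9)
  # structure of the destructive design: n = 3 tumor samples per time
  tum <- d[d$matrix == "tumor" & d$analyte == "total_mmae", ]
  expect_equal(as.integer(table(tum$time)), rep(3L, 3))
})

test_that("residual noise follows the combined-error standard deviation", {
  set.seed(99)
  Y <- 250
  draws <- adcpkpd:::.add_noise(rep(Y, 2000), sigma_int = 0,
                                sigma_slope = 0.1)
  expect_equal(sd(draws), 0.1 * Y, tolerance = 0.05)
  expect_true(all(draws >= 0))
  draws2 <- adcpkpd:::.add_noise(rep(Y, 2000), sigma_int = 5,
                                 sigma_slope = 0)
  expect_equal(sd(draws2), 5, tolerance = 0.05)
})

test_that("subject-level variability has the reported coefficient of variation", {
  set.seed(17)
  kmax_i <- p_n87$Kmax * adcpkpd:::.iiv_factors(10000, p_n87$iiv_Kmax)
  cv <- sd(kmax_i) / mean(kmax_i)
  expect_equal(cv, 0.1016, tolerance = 0.03)  # Monte-Carlo at n = 1e4
  tau_i <- p_n87$tau * adcpkpd:::.iiv_factors(10000, p_n87$iiv_tau)
  expect_equal(sd(tau_i) / mean(tau_i), 0.194, tolerance = 0.03)
})

test_that("TGI arms follow the design: controls shared, subjects vary with IIV", {
  des0 <- tgi_design("n87", doses = c(0, 10), n_per_arm = 3,
                     sigma_slope = 1e-12, iiv_Kmax = 0, iiv_tau = 0,
                     seed = 5)
  d0 <- generate_tgi_dataset(des0, p_n87)
  # zero IIV, zero noise: all subjects in an arm identical to the typical curve
  by_subj <- split(d0$value[d0$dose == 10], d0$subject[d0$dose == 10])
  expect_true(all(vapply(by_subj, function(v) isTRUE(all.equal(v, by_subj[[1]])),
                         logical(1))))
  ctrl <- d0[d0$dose == 0 & d0$subject == d0$subject[1], ]
  expect_equal(ctrl$value, 375 * exp(growth_rate(13.5) * ctrl$time),
               tolerance = 1e-9)

  desI <- tgi_design("n87", doses = c(0, 10), n_per_arm = 3,
                     sigma_slope = 1e-12, iiv_Kmax = 0.3, iiv_tau = 0.3,
                     seed = 5)
  dI <- generate_tgi_dataset(desI, p_n87)
  trt <- split(dI$value[dI$dose == 10], dI$subject[dI$dose == 10])
  expect_false(isTRUE(all.equal(trt[[1]], trt[[2]])))
  # control arms ignore PD variability entirely
  ctrlI <- split(dI$value[dI$dose == 0], dI$subject[dI$dose == 0])
  expect_equal(ctrlI[[1]], ctrlI[[2]], tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("measurements are censored at the volume cap", {
  des <- tgi_design("n87", doses = 0, n_per_arm = 2, sigma_slope = 1e-12,
                    cap = 1200, seed = 6)
  d <- generate_tgi_dataset(des, p_n87)
  for (s in unique(d$subject)) {
    v <- d$value[d$subject == s]
    expect_true(all(v[-length(v)] <= 1200))
  }
  expect_lt(max(d$time), 48)
})

test_that("generated analytes respect the payload mass hierarchy", {
  des <- pk_design("mcf7", sigma_slope = 1e-12, seed = 4)
  d <- generate_pk_dataset(des, p_mcf7)
  for (k in unique(paste(d$time, d$matrix, d$subject))) {
    rows <- d[paste(d$time, d$matrix, d$subject) == k, ]
    tot <- rows$value[rows$analyte == "total_mmae"]
    unc <- rows$value[rows$analyte == "unconjugated_mmae"]
    expect_gte(tot, unc - 1e-9)
  }
})
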