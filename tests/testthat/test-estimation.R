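# Build one small noiseless plasma dataset from model predictions so the
# likelihood identities can be checked exactly.
noiseless_plasma <- function(params = p_n87) {
  times <- c(10 / 1440, 1, 3, 7)
  sim <- simulate_adc(params, 10, times = sort(unique(c(0, times))),
                      mode = "pk", tv0 = 500)
  obs <- sim_observables(sim)
  d <- obs[obs$matrix == "plasma" & obs$time %in% times &
             obs$analyte %in% c("total_trastuzumab", "unconjugated_mmae",
                                "total_mmae"), ]
  d$model <- params$model; d$dose <- 10; d$subject <- "typ"
  d
}

test_that("the -2LL reduces to its textbook special cases", {
  d <- noiseless_plasma()
  config <- list(stage = "plasma", params = list(n87 = p_n87), tv0 = 500)
  # y == Y with unit variance: sum of log(1) = 0
  obj <- ml_objective(c(Kdec_P = 0.323), d, config,
                      var = list(sigma_int = 1, sigma_slope = 0))
  expect_equal(obj, 0, tolerance = 1e-6)
  # one observation off by exactly sigma_int: standardized residual of 1
  d1 <- d[1, ]
  d1$value <- d1$value + 2
  obj1 <- ml_objective(c(Kdec_P = 0.323), d1, config,
                       var = list(sigma_int = 2, sigma_slope = 0))
  expect_equal(obj1, 1 + log(4), tolerance = 1e-6)
})

test_that("the noiseless objective is minimized at the generating truth", {
  d <- noiseless_plasma()
  config <- list(stage = "plasma", params = list(n87 = p_n87), tv0 = 500)
  v <- list(sigma_int = 0, sigma_slope = 0.05)
  at_truth <- ml_objective(c(Kdec_P = 0.323), d, config, v)
  for (k in c(0.8, 0.9, 1.1, 1.25)) {
    expect_gt(ml_objective(c(Kdec_P = 0.323 * k), d, config, v), at_truth)
  }
})

test_that("simulation failure at a candidate returns a penalty, not an error", {
  d <- noiseless_plasma()
  config <- list(stage = "plasma", params = list(n87 = p_n87), tv0 = 500)
  expect_warning(val <- ml_objective(c(V1_ADC = -1), d, config), "failed")
  expect_equal(val, 1e10)
})

test_that("noiseless plasma refit recovers the deconjugation rate exactly", {
  d <- rbind(noiseless_plasma(p_n87), noiseless_plasma(p_mcf7))
  f <- fit_stage("plasma", d, p_n87, n_start = 1, compute_cv = FALSE,
                 rtol = 1e-7)
  expect_lt(abs(f$estimates[["Kdec_P"]] / 0.323 - 1), 0.01)
  expect_lt(abs(f$estimates[["CL_ADC"]] / 0.033 - 1), 0.01)
})

test_that("noiseless tumor refit recovers antigen density for both models", {
  for (m in c("n87", "mcf7")) {
    p <- adc_params(m)
    d <- generate_pk_dataset(pk_design(m, sigma_slope = 1e-10, seed = 1), p)
    f <- fit_stage("tumor", d, p, compute_cv = FALSE)
    expect_lt(abs(f$estimates[["Ag_ex"]] / p$Ag_ex - 1), 0.02)
  }
})

test_that("row order does not affect estimates", {
  d <- generate_pk_dataset(pk_design("n87", sigma_slope = 0.05, seed = 2),
                           p_n87)
  f1 <- fit_stage("tumor", d, p_n87, compute_cv = FALSE)
  set.seed(1)
  f2 <- fit_stage("tumor", d[sample(nrow(d)), ], p_n87, compute_cv = FALSE)
  expect_equal(f1$estimates, f2$estimates, tolerance = 1e-4)
})

test_that("jittered multi-starts agree on the plasma optimum", {
  d <- rbind(noiseless_plasma(p_n87), noiseless_plasma(p_mcf7))
  config <- list(stage = "plasma",
                 params = list(n87 = p_n87, mcf7 = p_mcf7), tv0 = 500)
  ests <- sapply(1:3, function(i) {
    set.seed(i + 10)
    init <- exp(log(c(0.033, 0.0585, 0.084, 0.051, 0.323)) +
                  rnorm(5, 0, 0.2))
    names(init) <- c("CL_ADC", "CLD_ADC", "V1_ADC", "V2_ADC", "Kdec_P")
    f <- fit_stage("plasma", d, p_n87, init = as.list(init), n_start = 1,
                   compute_cv = FALSE, rtol = 1e-6)
    f$estimates
  })
  spread <- apply(ests, 1, function(v) diff(range(v)) / mean(v))
  expect_lt(max(spread), 0.005)
})

test_that("misplacing KC50 measurably worsens the PD objective", {
  tgi <- rbind(
    generate_tgi_dataset(tgi_design("n87", n_per_arm = 2,
                                    sigma_slope = 0.05, seed = 8), p_n87),
    generate_tgi_dataset(tgi_design("mcf7", n_per_arm = 2,
                                    sigma_slope = 0.05, seed = 9), p_mcf7))
  config <- list(stage = "pd",
                 params = list(n87 = p_n87, mcf7 = p_mcf7), tv0 = 375,
                 rtol = 1e-6)
  at_truth <- ml_objective(c(Kmax = 1.03, KC50 = 96.8, tau = 2.03),
                           tgi, config)
  off <- ml_objective(c(Kmax = 1.03, KC50 = 80, tau = 2.03), tgi, config)
  expect_gt(off, at_truth + 10)
})

test_that("growth fits recover the doubling time from control arms", {
  d <- generate_tgi_dataset(tgi_design("mcf7", doses = 0, n_per_arm = 7,
                                       sigma_slope = 0.05, seed = 12),
                            p_mcf7)
  g <- fit_growth(d)
  expect_lt(abs(g$DT / 10.6 - 1), 0.05)
  expect_gt(g$TV0, 300); expect_lt(g$TV0, 450)
})

test_that("sequential calibration runs stages in order and tolerates gaps", {
  plasma <- rbind(noiseless_plasma(p_n87), noiseless_plasma(p_mcf7))
  tumor <- generate_pk_dataset(pk_design("n87", sigma_slope = 1e-10,
                                         seed = 14), p_n87)
  expect_message(
    res <- sequential_calibration(list(plasma = plasma, tumor = tumor),
                                  n_start = 1, compute_cv = FALSE,
                                  rtol = 1e-6),
    "PD stage skipped")
  expect_named(res$tumor, "n87")
  expect_lt(abs(res$params$n87$Ag_ex / 185000 - 1), 0.03)
  expect_lt(abs(res$params$n87$Kdec_P / 0.323 - 1), 0.02)
  # the PD stage refuses to run without the tumor stage
  tgi <- generate_tgi_dataset(tgi_design("n87", n_per_arm = 1,
                                         sigma_slope = 0.05, seed = 15),
                              p_n87)
  expect_error(sequential_calibration(list(tgi = tgi), n_start = 1),
               "tumor stage")
})
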