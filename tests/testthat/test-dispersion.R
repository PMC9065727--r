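test_that("R2eff from intensities inverts the exponential", {
  expect_equal(r2eff_from_intensities(80, 80, 0.04), 0)
  expect_equal(r2eff_from_intensities(100 / exp(1), 100, 0.04), 25)
  expect_error(r2eff_from_intensities(-1, 10), "positive")

  # round trip through Carver-Richards-generated intensities
  nu <- cpmg_field_schedule()
  r2 <- carver_richards(nu, dw_ppm_to_rads(2), 0.03, 500, 30)
  intens <- exp(-r2 * 0.04)
  expect_equal(r2eff_from_intensities(intens, 1, 0.04), r2,
               tolerance = 1e-9)
})

test_that("Carver-Richards limits: no exchange contrast and vanishing p_B", {
  nu <- cpmg_field_schedule()
  expect_equal(carver_richards(nu, 0, 0.05, 500, 22), rep(22, 10))
  expect_equal(carver_richards(nu, dw_ppm_to_rads(2), 1e-9, 500, 22),
               rep(22, 10), tolerance = 1e-4)
  # R2eff -> R2_0 at very high refocusing field
  expect_equal(carver_richards(1e6, dw_ppm_to_rads(2), 0.03, 500, 22), 22,
               tolerance = 1e-3)
})

test_that("closed form matches the Bloch-McConnell propagator", {
  nu <- cpmg_field_schedule()
  # the worked example regime
  dw <- dw_ppm_to_rads(2, 81.1e6)
  dev <- abs(carver_richards(nu, dw, 0.03, 500, 30) -
               r2eff_bloch_mcconnell(nu, dw, 0.03, 500, 30))
  expect_lt(max(dev), 0.5)
  # wider parameter sweep
  for (pb in c(0.02, 0.1, 0.2)) {
    for (kex in c(50, 500, 5000)) {
      for (dwp in c(1, 6)) {
        d <- dw_ppm_to_rads(dwp)
        expect_lt(max(abs(carver_richards(nu, d, pb, kex, 20) -
                            r2eff_bloch_mcconnell(nu, d, pb, kex, 20))),
                  0.5)
      }
    }
  }
  # the amplitude readout additionally carries end effects but stays close
  # in the dilute-minor-state regime
  amp <- r2eff_bloch_mcconnell(nu, dw, 0.03, 500, 30, readout = "amplitude")
  expect_lt(max(abs(carver_richards(nu, dw, 0.03, 500, 30) - amp)), 0.5)
})

test_that("dispersion is monotone in field and obeys the fast-exchange limit", {
  nu <- cpmg_field_schedule()
  for (pb in c(0.01, 0.1, 0.2)) {
    for (kex in c(50, 500, 5000)) {
      for (dwp in c(0.5, 3, 6)) {
        r2 <- carver_richards(nu, dw_ppm_to_rads(dwp), pb, kex, 20)
        expect_true(all(diff(r2) <= 1e-9))
      }
    }
  }
  # k_ex >= 20 dw: low-field Rex -> pA pB dw^2 / kex
  dw <- 500
  kex <- 20 * dw
  rex <- carver_richards(25, dw, 0.05, kex, 20) - 20
  expect_lt(abs(rex / (0.95 * 0.05 * dw^2 / kex) - 1), 0.1)
  # the overflow-safe low-field branch stays continuous
  expect_equal(carver_richards(0.01, dw, 0.05, kex, 20),
               carver_richards(25, dw, 0.05, kex, 20), tolerance = 1e-2)
})

test_that("global fit recovers exchange parameters", {
  # noise-free single curve: near-exact recovery
  m <- exchange_model(0.04, 600, dw = dw_ppm_to_rads(2.5), r2_0 = 21,
                      temperature = 30)
  curves <- simulate_dispersion(m, noise_sigma = 0, seed = 51)
  fit <- fit_dispersion_global(curves)
  expect_lt(fit$deviance, 1e-6)
  expect_equal(fit$models[["30"]]$k_ex, 600, tolerance = 0.01)
  expect_equal(fit$models[["30"]]$p_b, 0.04, tolerance = 0.01)
  expect_equal(fit$models[["30"]]$dw, dw_ppm_to_rads(2.5), tolerance = 0.01)

  # ten residues with noise: k_ex within 15%, pB dw^2 products within 20%
  m10 <- exchange_model(0.03, 500, dw = dw_ppm_to_rads(seq(1, 3, length = 10)),
                        r2_0 = seq(18, 30, length = 10), temperature = 30)
  curves10 <- simulate_dispersion(m10, noise_sigma = 0.3, seed = 52)
  fit10 <- fit_dispersion_global(curves10)
  est <- fit10$models[["30"]]
  expect_lt(abs(est$k_ex / 500 - 1), 0.15)
  prod_true <- 0.03 * dw_ppm_to_rads(seq(1, 3, length = 10))^2
  prod_est <- est$p_b * est$dw^2
  expect_lt(stats::median(abs(prod_est / prod_true - 1)), 0.2)

  # flat curves leave the exchange parameters unidentifiable
  flat <- exchange_model(0.03, 500, dw = c(0, 0), r2_0 = c(15, 25),
                         temperature = 30)
  fc <- simulate_dispersion(flat, noise_sigma = 0, seed = 53)
  expect_warning(fit_dispersion_global(fc), "unidentifiable")
})

test_that("multi-temperature sharing keeps dw common across temperatures", {
  dw <- dw_ppm_to_rads(c(1.5, 2, 2.5, 3))
  m30 <- exchange_model(0.03, 500, dw = dw, r2_0 = c(20, 22, 24, 26),
                        temperature = 30)
  m15 <- exchange_model(0.05, 100, dw = dw, r2_0 = c(24, 26, 28, 30),
                        temperature = 15)
  curves <- rbind(simulate_dispersion(m30, noise_sigma = 0.1, seed = 54),
                  simulate_dispersion(m15, noise_sigma = 0.1, seed = 55))
  fit <- fit_dispersion_global(curves, sharing = "default")
  expect_length(fit$models, 2)
  expect_equal(fit$models[["15"]]$dw, fit$models[["30"]]$dw) # shared
  expect_lt(abs(fit$models[["30"]]$k_ex / 500 - 1), 0.35)
  expect_lt(abs(fit$models[["15"]]$k_ex / 100 - 1), 0.6)
})

test_that("significance testing controls false positives and finds real exchange", {
  flat <- data.frame(nu_cpmg = cpmg_field_schedule(), r2eff = rep(20, 10),
                     err = rep(0.3, 10))
  s0 <- dispersion_significance(flat)
  expect_false(s0$is_significant)
  expect_equal(s0$rex, 0)

  set.seed(61)
  # null curves: false-positive rate stays at or under ~2%
  n_null <- 200
  fp <- vapply(seq_len(n_null), function(i) {
    cur <- data.frame(nu_cpmg = cpmg_field_schedule(),
                      r2eff = 20 + rnorm(10, 0, 0.3), err = rep(0.3, 10))
    dispersion_significance(cur)$is_significant
  }, logical(1))
  expect_lte(mean(fp), 0.02)

  # strong dispersion (Rex ~ 5 1/s) is essentially always detected
  m <- exchange_model(0.03, 500, dw = dw_ppm_to_rads(2.2), r2_0 = 20,
                      temperature = 30)
  hits <- vapply(1:40, function(i) {
    cur <- simulate_dispersion(m, noise_sigma = 0.3, mode = "r2eff",
                               seed = 6100 + i)
    dispersion_significance(cur)$is_significant
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("cpmg tables read back from rates and from intensities", {
  p <- tempfile(fileext = ".tsv")
  write.table(data.frame(residue = c(1, 1), temperature_C = 30,
                         nu_cpmg_hz = c(100, 1000), r2eff_s = c(25, 21),
                         err_s = 0.3),
              p, sep = "\t", quote = FALSE, row.names = FALSE)
  d <- read_cpmg_table(p)
  expect_equal(d$r2eff, c(25, 21))

  p2 <- tempfile(fileext = ".tsv")
  write.table(data.frame(residue = 1, temperature_C = 30,
                         nu_cpmg_hz = c(0, 100, 1000),
                         intensity = c(1, exp(-25 * 0.04), exp(-21 * 0.04))),
              p2, sep = "\t", quote = FALSE, row.names = FALSE)
  d2 <- read_cpmg_table(p2)
  expect_equal(d2$r2eff, c(25, 21), tolerance = 1e-9)
})
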