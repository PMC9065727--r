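test_that("RDCs are coupling differences with quadrature errors", {
  ja <- data.frame(resno = 1:3, j_hz = c(-92, -90, -95), err_hz = 1)
  ji <- data.frame(resno = 1:3, j_hz = c(-94, -90, -93), err_hz = 1)
  d <- rdc_from_couplings(ja, ji)
  expect_equal(d$rdc_hz, c(2, 0, -2))
  expect_equal(d$err_hz, rep(sqrt(2), 3))
  expect_equal(rdc_from_couplings(ja, ja)$rdc_hz, rep(0, 3))
  expect_error(rdc_from_couplings(ja, data.frame(resno = 9, j_hz = 1)),
               "no shared")
})

test_that("back-calculation honors axial and rhombic angular limits", {
  tz <- alignment_tensor(da = 5, rhombicity = 0)
  vz <- as_nh(data.frame(resno = 1, x = 0, y = 0, z = 1)) # theta = 0
  expect_equal(back_calc_rdc(tz, vz)$rdc_calc, 10) # 2 Da

  magic <- acos(1 / sqrt(3)) # 54.7356 deg
  vm <- as_nh(data.frame(resno = 1, x = sin(magic), y = 0, z = cos(magic)))
  expect_equal(back_calc_rdc(tz, vm)$rdc_calc, 0, tolerance = 1e-9)

  # two members with opposite angular terms cancel: theta=0 gives +2 Da;
  # theta=90, Phi=90 at rhombicity 2/3 gives -(1 + 3/2 * 2/3) = -2 Da
  t2 <- alignment_tensor(da = 5, rhombicity = 2 / 3)
  vy <- as_nh(data.frame(resno = 1, x = 0, y = 1, z = 0))
  both <- back_calc_rdc(list(tz, t2), list(vz, vy))
  expect_equal(both$rdc_calc, 0, tolerance = 1e-9)

  expect_error(back_calc_rdc(list(tz, t2), list(vz)), "one vector set")
})

test_that("printed angular form equals the general form at rhombicity 1-analog", {
  # the printed expression fixes the rhombic coefficient at 3/2; it matches
  # the Saupe route only for vectors in the tensor frame where the rhombic
  # term vanishes (theta = 0)
  t0 <- alignment_tensor(da = 7, rhombicity = 0.3, euler = c(0.4, 0.9, -0.2))
  R <- euler_zyz(0.4, 0.9, -0.2)
  vz <- as_nh(data.frame(resno = 1, x = R[1, 3], y = R[2, 3], z = R[3, 3]))
  expect_equal(back_calc_rdc(t0, vz, form = "printed")$rdc_calc,
               back_calc_rdc(t0, vz, form = "saupe")$rdc_calc,
               tolerance = 1e-9)
  # off-axis the two differ unless rhombicity happens to be 1
  set.seed(3)
  v <- as_nh(random_unit_vectors(8))
  expect_gt(max(abs(back_calc_rdc(t0, v, form = "printed")$rdc_calc -
                      back_calc_rdc(t0, v, form = "saupe")$rdc_calc)), 0.1)
})

test_that("SVD fit recovers a known tensor from noise-free data", {
  set.seed(21)
  v <- as_nh(random_unit_vectors(20))
  t0 <- random_tensor()
  pred <- back_calc_rdc(t0, v)
  obs <- rdc_set(pred$resno, pred$rdc_calc)
  fit <- svd_fit_tensor(obs, v)
  expect_lt(max(abs(fit$tensors[[1]]$saupe - t0$saupe)) / max(abs(t0$saupe)),
            1e-10)
  expect_lt(fit$r_factor, 1e-10)
  expect_equal(fit$n_params, 5L)

  zero <- svd_fit_tensor(rdc_set(pred$resno, rep(0, 20)), v)
  expect_equal(zero$tensors[[1]]$saupe, matrix(0, 3, 3), tolerance = 1e-12)

  expect_error(svd_fit_tensor(rdc_set(1:4, 1:4), v), "underdetermined")
})

test_that("single-conformer fit of ensemble-generated data misfits badly", {
  set.seed(22)
  e <- make_toy_ensemble(n_residues = 30, n_members = 3, loop = 8:20,
                         loop_disp = 12, seed = 31)
  tens <- lapply(1:3, function(k) random_tensor())
  obs <- simulate_rdcs(e, tens, noise_sigma = 0, seed = 32)
  single <- suppressWarnings(svd_fit_tensor(obs, e$members[[1]]))
  multi <- suppressWarnings(ensemble_fit(obs, e))
  # data are noise-free, so the misfit of the single-conformer model is
  # pure model error, orders of magnitude above the ensemble fit
  expect_gt(single$r_factor, 0.02)
  expect_lt(multi$r_factor, 1e-8)
  expect_gt(single$r_factor, 1e4 * multi$r_factor)
})

test_that("R-factor arithmetic and invariances", {
  obs <- rdc_set(1:3, c(3, -4, 5))
  expect_equal(r_factor(obs, c(3, -4, 5)), 0)
  expect_equal(r_factor(obs, rep(0, 3)), 1 / sqrt(2))
  expect_equal(r_factor(rdc_set(1, 10), 8), sqrt(4 / 200))
  expect_error(r_factor(rdc_set(1:2, c(0, 0)), c(1, 1)), "undefined")

  # invariant under joint rescaling of obs and calc
  set.seed(5)
  o <- rnorm(10, sd = 8); c0 <- o + rnorm(10)
  r1 <- r_factor(rdc_set(1:10, o), c0)
  expect_equal(r_factor(rdc_set(1:10, -2.7 * o), -2.7 * c0), r1)
})

test_that("joint ensemble fit nests the single-tensor fit", {
  set.seed(23)
  e <- make_toy_ensemble(n_residues = 30, n_members = 2, loop = 8:20,
                         loop_disp = 10, seed = 41)
  v1 <- extract_nh_vectors(e$members[[1]])
  t0 <- random_tensor()
  pred <- back_calc_rdc(t0, v1)
  obs <- rdc_set(pred$resno, pred$rdc_calc + rnorm(nrow(pred), 0, 1.5),
                 rep(1.5, nrow(pred)))
  f1 <- svd_fit_tensor(obs, v1)
  f1b <- ensemble_fit(obs, list(v1))
  expect_equal(f1b$r_factor, f1$r_factor, tolerance = 1e-10)
  expect_equal(f1b$tensors[[1]]$saupe, f1$tensors[[1]]$saupe,
               tolerance = 1e-10)
  f2 <- suppressWarnings(ensemble_fit(obs, e))
  expect_lte(f2$r_factor, f1$r_factor + 1e-12) # nested least squares
})

test_that("fitted R-factor tracks the noise model", {
  # with Gaussian noise sigma, fitted R ~ sigma / (sqrt(2) rms(obs))
  set.seed(24)
  v <- extract_nh_vectors(make_toy_ensemble(n_members = 1)$members[[1]])
  t0 <- random_tensor()
  clean <- back_calc_rdc(t0, v)
  sigma <- 2
  expected <- sigma / (sqrt(2) * sqrt(mean(clean$rdc_calc^2)))
  rf <- replicate(100, {
    obs <- rdc_set(clean$resno, clean$rdc_calc + rnorm(nrow(clean), 0, sigma))
    svd_fit_tensor(obs, v)$r_factor
  })
  expect_lt(abs(mean(rf) - expected), 0.3 * expected)
})

test_that("ensemble-size selection finds planted conformers", {
  set.seed(25)
  identical_pool <- conformer_ensemble(rep(list(
    build_backbone(rep(-57, 20), rep(-47, 20))), 4))
  v <- extract_nh_vectors(identical_pool$members[[1]])
  t0 <- random_tensor()
  pred <- back_calc_rdc(t0, v)
  expect_warning(
    res0 <- select_ensemble_size(identical_pool,
                                 rdc_set(pred$resno, pred$rdc_calc),
                                 k_max = 4),
    "truncated")
  expect_equal(res0$k_star, 1L)

  pool <- make_conformer_pool(n_planted = 3, decoys_per = 3, seed = 7)
  tens <- lapply(1:3, function(k) random_tensor())
  obs <- simulate_rdcs(conformer_ensemble(pool$pool$members[pool$planted]),
                       tens, noise_sigma = 0, seed = 8)
  res <- select_ensemble_size(pool$pool, obs, k_max = 7)
  expect_gte(res$k_star, 3L)
  expect_lt(res$fit$r_factor, 1e-6)
  expect_true(all(diff(res$curve$r_factor) <= 1e-12))
})

test_that("per-domain fits operate on residue subsets", {
  set.seed(26)
  v <- as_nh(random_unit_vectors(24))
  t0 <- random_tensor()
  pred <- back_calc_rdc(t0, v)
  obs <- rdc_set(pred$resno, pred$rdc_calc)
  dom <- subset_rdc_set(obs, 1:12)
  expect_equal(nrow(dom), 12)
  fitd <- svd_fit_tensor(dom, v)
  expect_equal(fitd$n_data, 12L)
  expect_equal(fitd$tensors[[1]]$saupe, t0$saupe, tolerance = 1e-8)
  expect_error(subset_rdc_set(obs, 100:120), "subset")
})

test_that("rdc tables round-trip through TSV", {
  x <- rdc_set(c(3, 7, 9), c(1.5, -2.25, 8), c(1, 1.5, 2))
  p <- tempfile(fileext = ".tsv")
  write_rdc_table(x, p)
  y <- read_rdc_table(p)
  expect_equal(y$resno, x$resno)
  expect_equal(y$rdc_hz, x$rdc_hz)
  expect_equal(y$err_hz, x$err_hz)
})
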