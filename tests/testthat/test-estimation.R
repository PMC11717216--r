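test_that("the cost function matches its definition", {
  expect_equal(cost_function(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cost_function(1.1, 1.0), 0.01)
  # brute-force oracle on random vectors, with and without the anchor
  set.seed(23)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    obs <- runif(n, 0.1, 2); pred <- runif(n, 0.1, 2)
    oracle <- 0
    for (j in seq_len(n)) oracle <- oracle + ((obs[j] - pred[j]) / pred[j])^2
    expect_equal(cost_function(obs, pred), oracle)
    kp_o <- runif(1, 0.1, 5); kp_p <- runif(1, 0.1, 5)
    expect_equal(cost_function(obs, pred, kpuu_obs = kp_o, kpuu_pred = kp_p),
                 oracle + ((kp_o - kp_p) / kp_p)^2)
  }
})

test_that("non-positive predictions are penalised finitely, never NaN", {
  val <- cost_function(c(1, 1), c(1, -0.1))
  expect_true(is.finite(val))
  expect_true(attr(val, "penalised"))
  expect_gt(as.numeric(val), 1e6)
})

test_that("Kp_uu prediction follows the AUC-ratio identity", {
  # tissue curve identical to media and equal unbound fractions: Kp_uu = 1
  times <- seq(0, 100, by = 5)
  base <- exp(-0.01 * times)
  traj <- structure(data.frame(time_min = times, C_m = base, C_i = base / 2,
                               C_c = base / 2),
                    class = c("ct_trajectory", "data.frame"))
  expect_equal(predict_kpuu(traj, fu_cell = 1, fu_media = 1), 1)
  expect_equal(predict_kpuu(traj, fu_cell = 0.5, fu_media = 1), 0.5)
  # refined-grid oracle on simulated systems: the standard 101-point graded
  # grid must agree with a 20x finer integration to within 0.1%
  set.seed(29)
  for (i in 1:5) {
    p <- ct_random_params()
    coarse <- solve_analytic(p, c0 = 1, times = ct_auc_grid(360, 101))
    fine <- solve_analytic(p, c0 = 1, times = ct_auc_grid(360, 2001))
    expect_equal(predict_kpuu(coarse, 0.7, 0.5), predict_kpuu(fine, 0.7, 0.5),
                 tolerance = 1e-3)
  }
})

test_that("the scaling factor is the observed/predicted Kp_uu ratio", {
  expect_equal(scaling_factor(1, 1), 1)
  expect_equal(scaling_factor(2, 0.5), 4)
  # 2D suspension-to-human anchor scaling: observed = 4.9 x predicted
  expect_equal(scaling_factor(4.9 * 0.37, 0.37), 4.9)
  expect_error(scaling_factor(0, 1), "> 0")
  expect_error(scaling_factor(1, -2), "> 0")
})

test_that("noiseless synthetic data are recovered to high accuracy", {
  chip <- ct_test_chip()
  cmp <- ct_test_compound(logp = 3, fu = 0.5)
  ex <- generate_depletion(chip, cmp, cl_c = 0.03, noise = "none", seed = 5)
  fit <- fit_twin(ex$observed, chip, cmp,
                  options = ct_fit_options(kpuu_obs = ex$truth$kpuu,
                                           n_starts = 3, seed = 2))
  expect_true(fit$converged)
  expect_lt(abs(fit$cl_c_hat / 0.03 - 1), 0.01)
  expect_lt(abs(fit$sa_hat / chip$sa_med_int_liver_cm2 - 1), 0.05)
  expect_lt(fit$ssq, 1e-6)
  # objective never increased relative to the start of the winning run
  expect_lte(fit$ssq, fit$ssq_initial)
  expect_false(fit$identifiability_warning)
})

test_that("under multiplicative noise the minimised objective scales as n * cv^2", {
  # with cv-level relative noise on n points, the best achievable sum of
  # squared relative residuals concentrates near (n - p) * cv^2; fits to
  # noisy data cannot beat the noise floor
  chip <- ct_test_chip()
  cmp <- ct_test_compound(logp = 3, fu = 0.5)
  cv <- 0.1
  ssqs <- vapply(1:15, function(r) {
    ex <- generate_depletion(chip, cmp, cl_c = 0.03, noise = "lognormal",
                             cv = cv, seed = 300 + r)
    fit_twin(ex$observed, chip, cmp,
             options = ct_fit_options(kpuu_obs = ex$truth$kpuu,
                                      n_starts = 2, seed = r))$ssq
  }, 0)
  n_pts <- 8
  expect_gt(median(ssqs), 0.2 * n_pts * cv^2)
  expect_lt(median(ssqs), 3 * n_pts * cv^2)
})

test_that("estimation is reproducible for identical seeds and differs across seeds", {
  chip <- ct_test_chip()
  cmp <- ct_test_compound(logp = 3, fu = 0.5)
  ex <- generate_depletion(chip, cmp, cl_c = 0.02, noise = "lognormal",
                           cv = 0.1, seed = 9)
  opt <- ct_fit_options(kpuu_obs = ex$truth$kpuu, n_starts = 2, seed = 4)
  f1 <- fit_twin(ex$observed, chip, cmp, options = opt)
  f2 <- fit_twin(ex$observed, chip, cmp, options = opt)
  expect_identical(f1$cl_c_hat, f2$cl_c_hat)
  expect_identical(f1$starts, f2$starts)
})

test_that("clearance-only estimation works through the Brent branch", {
  chip <- ct_test_chip()
  cmp <- ct_test_compound(logp = 3, fu = 0.5)
  ex <- generate_depletion(chip, cmp, cl_c = 0.05, noise = "none", seed = 3)
  fit <- fit_twin(ex$observed, chip, cmp, free_params = "CL_c",
                  options = ct_fit_options(kpuu_obs = ex$truth$kpuu,
                                           n_starts = 2, seed = 1))
  expect_lt(abs(fit$cl_c_hat / 0.05 - 1), 0.01)
})

test_that("without an observed Kp_uu the anchor grid is scanned and reported", {
  chip <- ct_test_chip()
  cmp <- ct_test_compound(logp = 3, fu = 0.5)
  ex <- generate_depletion(chip, cmp, cl_c = 0.03, noise = "none", seed = 5)
  fit <- fit_twin(ex$observed, chip, cmp,
                  options = ct_fit_options(anchor = "grid", n_starts = 2, seed = 2))
  expect_identical(fit$kpuu_source, "grid")
  expect_s3_class(fit$kpuu_grid, "data.frame")
  expect_equal(nrow(fit$kpuu_grid), length(ct_constants()$kpuu_grid))
  expect_true(fit$kpuu_obs %in% fit$kpuu_grid$kpuu_obs)
})

test_that("fit input validation is explicit", {
  chip <- ct_test_chip()
  cmp <- ct_test_compound()
  obs <- data.frame(time_min = c(0, 30), conc_umol_per_ml = c(1, 0.8))
  expect_error(fit_twin(obs, chip, cmp), "3 observation times")
  obs4 <- data.frame(time_min = c(10, 30, 60), conc_umol_per_ml = c(1, 0.8, 0.6))
  expect_error(fit_twin(obs4, chip, cmp), "t = 0")
  expect_error(fit_twin(rbind(obs4, data.frame(time_min = 0, conc_umol_per_ml = 1)),
                        chip, cmp, free_params = "banana"), "free_params")
})

test_that("fit reports serialise to JSON with the full audit trail", {
  chip <- ct_test_chip()
  cmp <- ct_test_compound(logp = 3, fu = 0.5)
  ex <- generate_depletion(chip, cmp, cl_c = 0.03, noise = "none", seed = 5)
  fit <- fit_twin(ex$observed, chip, cmp,
                  options = ct_fit_options(kpuu_obs = ex$truth$kpuu,
                                           n_starts = 2, seed = 7))
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_fit_report(fit, path)
  rep <- jsonlite::read_json(path)
  expect_equal(rep$cl_c_hat, fit$cl_c_hat)
  expect_equal(rep$seed, 7)
  expect_equal(rep$options$n_starts, 2)
})
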