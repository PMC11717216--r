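test_that("rate constants follow their defining products and quotients", {
  chip <- ct_test_chip()
  pp <- list(P_endothelial = 1, K_int_med = 1, K_water_int = 1,
             K_water_cell = 1, PA_int_cell = 1, PA_cell_int = 1)
  p <- build_rate_constants(pp, chip, fu_media = 1, sa_med_int_liver_cm2 = 1)
  expect_equal(p$k1, 1)
  expect_equal(p$k2, 1)
  pp$K_int_med <- 2
  expect_equal(build_rate_constants(pp, chip, fu_media = 1,
                                    sa_med_int_liver_cm2 = 1)$k2, 0.5)
  set.seed(41)
  for (i in 1:20) {
    pp <- list(P_endothelial = runif(1, 1e-4, 0.1), K_int_med = runif(1, 0.5, 5),
               K_water_int = runif(1, 0.5, 5), K_water_cell = runif(1, 0.5, 50),
               PA_int_cell = runif(1, 1e-3, 0.1), PA_cell_int = runif(1, 1e-3, 0.1))
    fu <- runif(1, 0.05, 1); sa <- runif(1, 0.1, 5)
    p <- build_rate_constants(pp, chip, fu_media = fu, sa_med_int_liver_cm2 = sa)
    expect_equal(p$k1, fu * pp$P_endothelial * sa)
    expect_equal(p$k2, p$k1 / pp$K_int_med)
    expect_equal(p$k3, pp$K_water_int * pp$PA_int_cell)
    expect_equal(p$k4, pp$K_water_cell * pp$PA_cell_int)
  }
})

test_that("an unresolved exchange area points the user at estimation mode", {
  chip <- load_chip_preset("cnbio", sa_med_int_liver_cm2 = NA)
  pp <- compound_parameter_set(ct_test_compound(), chip)
  expect_error(build_rate_constants(pp, chip, fu_media = 0.5), "estimate")
})

test_that("the system matrix has the stated structure and spectrum", {
  p <- twin_parameters(k1 = 0.02, k2 = 0.01, k3 = 0.08, k4 = 0.7, cl_c = 0.03,
                       v_m = 1.6, v_i = 2e-4, v_c = 1e-3)
  a <- build_system_matrix(p)
  expect_equal(dim(a), c(3L, 3L))
  expect_equal(a[1, ], c(media = -p$k1 / p$v_m, interstitium = p$k2 / p$v_m,
                         intracellular = 0))
  expect_equal(unname(a[2, ]), c(p$k1 / p$v_i, -(p$k2 + p$k3) / p$v_i, p$k4 / p$v_i))
  expect_equal(unname(a[3, ]), c(0, p$k3 / p$v_c, -(p$k4 + p$cl_c) / p$v_c))
  # all-zero rates give the zero matrix
  p0 <- twin_parameters(0, 0, 0, 0, 0, 1, 1, 1)
  expect_true(all(build_system_matrix(p0) == 0))
  # randomized positive parameters: eigenvalues never in the right half plane
  set.seed(7)
  for (i in 1:25) {
    ev <- eigen(build_system_matrix(ct_random_params()), only.values = TRUE)$values
    expect_lte(max(Re(ev)), 1e-10)
  }
})

test_that("with clearance off the volume vector is a left null-vector (mass conserved)", {
  set.seed(11)
  for (i in 1:10) {
    p <- ct_random_params(cl_c = 0)
    a <- build_system_matrix(p)
    vols <- c(p$v_m, p$v_i, p$v_c)
    expect_equal(max(abs(vols %*% a)), 0, tolerance = 1e-12)
  }
})

test_that("the decoupled system stays at its initial state", {
  p <- twin_parameters(0, 0, 0, 0, 0, 1, 1, 1)
  traj <- solve_analytic(p, c0 = c(1, 0, 0), times = seq(0, 100, by = 10))
  expect_equal(traj$C_m, rep(1, 11))
  expect_equal(traj$C_i, rep(0, 11))
  expect_equal(traj$C_c, rep(0, 11))
})

test_that("trajectories conserve mass without clearance and deplete with it", {
  set.seed(13)
  for (i in 1:10) {
    p <- ct_random_params(cl_c = 0)
    traj <- solve_analytic(p, c0 = 1, times = seq(0, 360, by = 20))
    m <- total_mass(traj, p)
    expect_lt(max(abs(m - m[1])) / m[1], 1e-9)
    expect_true(all(traj$C_m > -1e-12 & traj$C_i > -1e-12 & traj$C_c > -1e-12))
  }
  for (i in 1:10) {
    p <- ct_random_params(cl_c = runif(1, 0.01, 0.2))
    m <- total_mass(solve_analytic(p, c0 = 1, times = seq(0, 360, by = 20)), p)
    expect_true(all(diff(m) < 0))
  }
})

test_that("analytic and numeric solvers agree to high accuracy", {
  set.seed(17)
  for (i in 1:20) {
    p <- ct_random_params()
    times <- seq(0, 360, length.out = 25)
    ta <- solve_analytic(p, c0 = 1, times = times)
    tn <- solve_numeric(p, c0 = 1, times = times, rtol = 1e-10, atol = 1e-12)
    expect_lt(ct_traj_rel_diff(ta, tn), 1e-6)
  }
})

test_that("near-defective systems fall back to the numeric solver with a note", {
  p <- ct_random_params()
  expect_message(traj <- solve_analytic(p, c0 = 1, times = seq(0, 60, by = 10),
                                        cond_max = 1e-12),
                 "falling back")
  expect_identical(attr(traj, "solver"), "numeric")
})

test_that("the single-compartment reduction is a pure exponential", {
  p <- twin_parameters(k1 = 0.05, k2 = 0, k3 = 0, k4 = 0, cl_c = 0,
                       v_m = 0.5, v_i = 1e-3, v_c = 1e-3)
  times <- seq(0, 120, by = 10)
  traj <- solve_numeric(p, c0 = c(2, 0, 0), times = times)
  expect_equal(traj$C_m, 2 * exp(-0.05 * times / 0.5), tolerance = 1e-7)
})

test_that("a degenerate single-point grid returns the initial state only", {
  p <- ct_random_params()
  traj <- solve_numeric(p, c0 = c(1, 0, 0), times = 0)
  expect_equal(nrow(traj), 1L)
  expect_equal(traj$C_m, 1)
})

test_that("fast exchange collapses to a one-compartment model with pooled volume", {
  # k1 = k2 (unit partition), all exchange >> clearance: after the initial
  # redistribution of the dose into the pooled volume, media follows the
  # one-compartment solution with V = V_m + V_i + V_c within 5%
  p <- twin_parameters(k1 = 1e3, k2 = 1e3, k3 = 1e3, k4 = 1e3, cl_c = 0.5,
                       v_m = 1, v_i = 0.2, v_c = 0.3)
  times <- seq(0, 10, by = 0.5)
  traj <- solve_numeric(p, c0 = 1, times = times)
  ref <- (1 / 1.5) * exp(-0.5 * times / 1.5)   # dose V_m C0 = 1 over 1.5 mL
  expect_lt(max(abs(traj$C_m[-1] - ref[-1]) / ref[-1]), 0.05)
})

test_that("two-chamber chips exchange via the mixing flow and conserve mass", {
  chip <- load_chip_preset("javelin")
  pp <- compound_parameter_set(ct_test_compound(), chip)
  p <- build_rate_constants(pp, chip, fu_media = 0.5, cl_c = 0)
  a <- build_system_matrix(p)
  expect_equal(dim(a), c(4L, 4L))
  expect_equal(a["media2", "media1"], chip$q_mix_ml_min / (chip$media_volume_ml / 2))
  traj <- solve_analytic(p, c0 = 1, times = seq(0, 360, by = 30))
  m <- total_mass(traj, p)
  expect_lt(max(abs(m - m[1])) / m[1], 1e-9)
  ta <- solve_analytic(p, c0 = 1, times = seq(0, 360, by = 30))
  tn <- solve_numeric(p, c0 = 1, times = seq(0, 360, by = 30), rtol = 1e-10, atol = 1e-12)
  expect_lt(ct_traj_rel_diff(ta, tn), 1e-6)
})

test_that("one-compartment fit recovers exact log-linear kinetics", {
  times <- c(0, 15, 30, 60, 120, 240)
  obs <- data.frame(time_min = times, conc_umol_per_ml = 2 * exp(-0.1 * times))
  fit <- fit_one_compartment(obs, v_ml = 1)
  expect_equal(fit$cl_c_ml_min, 0.1, tolerance = 1e-10)
  expect_equal(fit$c0, 2, tolerance = 1e-10)
  # half-life identity: with V = 1 mL and CL = ln 2 mL/min, C(1 min) = C0/2
  fit2 <- fit_one_compartment(
    data.frame(time_min = c(0, 1, 2),
               conc_umol_per_ml = exp(-log(2) * c(0, 1, 2))), v_ml = 1)
  expect_equal(fit2$cl_c_ml_min, log(2), tolerance = 1e-10)
  expect_equal(fit2$half_life_min, 1, tolerance = 1e-10)
})

test_that("one-compartment fit rejects invalid input", {
  expect_error(fit_one_compartment(
    data.frame(time_min = 0, conc_umol_per_ml = 1), v_ml = 1), "2 time points")
  expect_error(fit_one_compartment(
    data.frame(time_min = c(0, 10), conc_umol_per_ml = c(1, -1)), v_ml = 1),
    "> 0")
})

test_that("one-compartment fit is median-accurate under multiplicative noise", {
  set.seed(101)
  times <- c(0, 15, 30, 60, 120, 240, 360)
  cl_true <- 0.005; v <- 1
  ests <- replicate(200, {
    eps <- exp(rnorm(length(times), 0, sqrt(log(1 + 0.1^2))))
    obs <- data.frame(time_min = times,
                      conc_umol_per_ml = exp(-cl_true * times / v) * eps)
    fit_one_compartment(obs, v_ml = v)$cl_c_ml_min
  })
  expect_lt(abs(median(ests) / cl_true - 1), 0.02)
})
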