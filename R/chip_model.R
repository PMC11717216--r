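#' Kinetic parameters of the three-compartment chip model
#'
#' Bundles the four exchange rate constants, the intrinsic on-chip clearance
#' and the compartment volumes of the media / interstitium / intracellular
#' model. The rate constants are built from the compound's partition and
#' permeability parameters:
#' `k1 = fu_media * P_endothelial * SA_med_int_liver` (media -> interstitium
#' uptake, mL/min), `k2 = k1 / K_int_med` (back-transfer),
#' `k3 = K_water_int * PA_int_cell` (interstitium -> cell) and
#' `k4 = K_water_cell * PA_cell_int` (cell -> interstitium).
#'
#' @param k1,k2,k3,k4 exchange rate constants (mL/min), all >= 0.
#' @param cl_c intrinsic on-chip clearance (mL/min), >= 0.
#' @param v_m,v_i,v_c media, interstitial and intracellular volumes (mL).
#' @param fu_media fraction unbound in media.
#' @param n_media_chambers,q_mix_ml_min media chamber layout; with two
#'   chambers the media volume is split in half and the chambers exchange at
#'   `q_mix_ml_min`, with cells attached to chamber 1.
#' @return Object of class `twin_parameters`.
#' @export
twin_parameters <- function(k1, k2, k3, k4, cl_c, v_m, v_i, v_c, fu_media = 1,
                            n_media_chambers = 1, q_mix_ml_min = 0) {
  ks <- c(k1 = k1, k2 = k2, k3 = k3, k4 = k4)
  if (any(!is.finite(ks)) || any(ks < 0)) stop("rate constants must be finite and >= 0", call. = FALSE)
  if (!is.finite(cl_c) || cl_c < 0) stop("cl_c must be finite and >= 0", call. = FALSE)
  vols <- c(v_m = v_m, v_i = v_i, v_c = v_c)
  if (any(!is.finite(vols)) || any(vols <= 0)) stop("volumes must be finite and > 0", call. = FALSE)
  structure(list(k1 = k1, k2 = k2, k3 = k3, k4 = k4, cl_c = cl_c,
                 v_m = v_m, v_i = v_i, v_c = v_c, fu_media = fu_media,
                 n_media_chambers = as.integer(n_media_chambers),
                 q_mix_ml_min = q_mix_ml_min),
            class = "twin_parameters")
}

#' Assemble rate constants from compound and chip parameters
#'
#' @param pp a `partition_permeability_set` (see [compound_parameter_set()])
#'   or any list with elements `P_endothelial`, `K_int_med`, `K_water_int`,
#'   `K_water_cell`, `PA_int_cell`, `PA_cell_int`.
#' @param chip a complete [chip_spec()].
#' @param fu_media fraction unbound in the media.
#' @param cl_c intrinsic on-chip clearance (mL/min).
#' @param sa_med_int_liver_cm2 media/interstitium exchange area; defaults to
#'   the chip value and must be resolved (a preset nominal or an estimated
#'   value) before the model can be built.
#' @return A [twin_parameters()] object.
#' @export
build_rate_constants <- function(pp, chip, fu_media, cl_c = 0,
                                 sa_med_int_liver_cm2 = chip$sa_med_int_liver_cm2) {
  validate_chip_spec(chip, require_complete = FALSE)
  if (!is.finite(sa_med_int_liver_cm2) || sa_med_int_liver_cm2 <= 0)
    stop("SA_med_int_liver is unresolved for this chip; supply a value or estimate it with fit_twin(free_params = c('CL_c', 'SA_med_int_liver'))",
         call. = FALSE)
  for (f in c("media_volume_ml", "v_interstitium_ml", "v_intracellular_ml"))
    if (!is.finite(chip[[f]]))
      stop(sprintf("chip '%s': '%s' must be resolved before building the model", chip$name, f), call. = FALSE)
  k1 <- fu_media * pp$P_endothelial * sa_med_int_liver_cm2
  twin_parameters(k1 = k1,
                  k2 = k1 / pp$K_int_med,
                  k3 = pp$K_water_int * pp$PA_int_cell,
                  k4 = pp$K_water_cell * pp$PA_cell_int,
                  cl_c = cl_c,
                  v_m = chip$media_volume_ml,
                  v_i = chip$v_interstitium_ml,
                  v_c = chip$v_intracellular_ml,
                  fu_media = fu_media,
                  n_media_chambers = chip$n_media_chambers,
                  q_mix_ml_min = chip$q_mix_ml_min)
}

#' System matrix of the linear compartment model
#'
#' Builds the rate matrix `A` of `dC/dt = A C`. For a single media chamber
#' the state is `(C_m, C_i, C_c)` and
#' \deqn{A = \begin{pmatrix} -k_1/V_m & k_2/V_m & 0 \\
#'   k_1/V_i & -(k_2+k_3)/V_i & k_4/V_i \\
#'   0 & k_3/V_c & -(k_4 + CL_c)/V_c \end{pmatrix}}
#' For two media chambers the state is `(C_m1, C_m2, C_i, C_c)`: the media
#' volume splits in half, the chambers exchange at the mixing flow rate and
#' the cell layer sits under chamber 1. With `CL_c = 0` the volume vector is
#' a left null-vector of `A` (mass is conserved); all eigenvalues have
#' non-positive real part.
#'
#' @param p a [twin_parameters()] object.
#' @return Square numeric matrix with row/column names.
#' @export
build_system_matrix <- function(p) {
  stopifnot(inherits(p, "twin_parameters"))
  with(p, {
    if (n_media_chambers == 1L) {
      a <- matrix(c(-k1 / v_m,            k2 / v_m,          0,
                    k1 / v_i,  -(k2 + k3) / v_i,             k4 / v_i,
                    0,                    k3 / v_c, -(k4 + cl_c) / v_c),
                  nrow = 3, byrow = TRUE,
                  dimnames = rep(list(c("media", "interstitium", "intracellular")), 2))
    } else {
      vm1 <- v_m / 2; vm2 <- v_m / 2; q <- q_mix_ml_min
      a <- matrix(c(-(k1 + q) / vm1,  q / vm1,          k2 / vm1,           0,
                    q / vm2,         -q / vm2,          0,                  0,
                    k1 / v_i,         0,      -(k2 + k3) / v_i,             k4 / v_i,
                    0,                0,                 k3 / v_c, -(k4 + cl_c) / v_c),
                  nrow = 4, byrow = TRUE,
                  dimnames = rep(list(c("media1", "media2", "interstitium", "intracellular")), 2))
    }
    if (any(!is.finite(a))) stop("system matrix has non-finite entries", call. = FALSE)
    a
  })
}

# compartment volumes aligned with the state vector of build_system_matrix
.ct_state_volumes <- function(p) {
  if (p$n_media_chambers == 1L) c(p$v_m, p$v_i, p$v_c)
  else c(p$v_m / 2, p$v_m / 2, p$v_i, p$v_c)
}

# expand a (media, ist, cell) initial concentration to the full state
.ct_expand_c0 <- function(p, c0) {
  if (length(c0) == 1L) c0 <- c(c0, 0, 0)
  stopifnot(length(c0) == 3L)
  if (p$n_media_chambers == 1L) c0 else c(c0[1], c0[1], c0[2], c0[3])
}

# collapse a state matrix (states x times) to media/ist/cell concentrations
.ct_collapse_states <- function(p, cc) {
  if (p$n_media_chambers == 1L) {
    list(C_m = cc[1, ], C_i = cc[2, ], C_c = cc[3, ])
  } else {
    list(C_m = (cc[1, ] + cc[2, ]) / 2,  # equal chamber volumes
         C_i = cc[3, ], C_c = cc[4, ])
  }
}

.ct_trajectory <- function(times, conc, solver) {
  structure(data.frame(time_min = times, C_m = conc$C_m, C_i = conc$C_i,
                       C_c = conc$C_c),
            solver = solver, class = c("ct_trajectory", "data.frame"))
}

#' Solve the chip model analytically by eigendecomposition
#'
#' Diagonalises the system matrix and evaluates
#' `C(t) = X exp(L t) X^-1 C0`. If the eigenvector matrix is
#' ill-conditioned (condition number above `cond_max`, i.e. the matrix is
#' near-defective) the solver falls back to [solve_numeric()] and tags the
#' trajectory accordingly.
#'
#' @param p a [twin_parameters()] object.
#' @param c0 initial concentrations (media, interstitium, intracellular), in
#'   umol/mL; a single number is taken as the media concentration with empty
#'   tissue compartments.
#' @param times time grid in minutes (non-negative, increasing).
#' @param cond_max eigenvector condition-number threshold for the numeric
#'   fallback.
#' @return A `ct_trajectory` data frame with columns `time_min`, `C_m`,
#'   `C_i`, `C_c` and a `solver` attribute (`"analytic"` or `"numeric"`).
#' @export
solve_analytic <- function(p, c0 = 1, times = seq(0, 360, by = 5),
                           cond_max = 1e8) {
  stopifnot(inherits(p, "twin_parameters"))
  times <- as.numeric(times)
  if (any(diff(times) <= 0) || any(times < 0)) stop("times must be non-negative and strictly increasing", call. = FALSE)
  a <- build_system_matrix(p)
  x0 <- .ct_expand_c0(p, c0)
  eg <- eigen(a)
  cond <- tryCatch(kappa(eg$vectors, exact = TRUE), error = function(e) Inf)
  if (!all(is.finite(Mod(eg$values))) || cond > cond_max) {
    message(sprintf("eigenvector matrix condition number %.3g exceeds %.3g; falling back to numeric solver", cond, cond_max))
    return(solve_numeric(p, c0, times))
  }
  w <- solve(eg$vectors, x0)
  ex <- exp(outer(eg$values, times))              # n_state x n_times
  cc <- Re(eg$vectors %*% (ex * w))
  .ct_trajectory(times, .ct_collapse_states(p, cc), "analytic")
}

#' Solve the chip model numerically
#'
#' Stiff numerical integration of the same linear system with
#' [deSolve::lsoda()]; used as the robust fallback for near-defective
#' systems and as an independent cross-check of the analytic solver.
#'
#' @inheritParams solve_analytic
#' @param rtol,atol relative and absolute integration tolerances.
#' @return A `ct_trajectory` (see [solve_analytic()]).
#' @export
solve_numeric <- function(p, c0 = 1, times = seq(0, 360, by = 5),
                          rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(p, "twin_parameters"))
  times <- as.numeric(times)
  if (any(diff(times) <= 0) || any(times < 0)) stop("times must be non-negative and strictly increasing", call. = FALSE)
  a <- build_system_matrix(p)
  x0 <- .ct_expand_c0(p, c0)
  if (length(times) == 1L) {   # degenerate grid: nothing beyond t = 0
    if (times != 0) stop("a single-point grid must be t = 0", call. = FALSE)
    conc <- .ct_collapse_states(p, matrix(x0, ncol = 1))
    return(.ct_trajectory(times, conc, "numeric"))
  }
  t_solve <- if (times[1] > 0) c(0, times) else times
  out <- deSolve::lsoda(y = x0, times = t_solve,
                        func = function(t, y, parms) list(as.vector(parms %*% y)),
                        parms = a, rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0)
    stop("numeric integration failed; diagnostics: istate = ",
         attr(out, "istate")[1], call. = FALSE)
  cc <- t(unclass(out)[, -1, drop = FALSE])
  if (times[1] > 0) cc <- cc[, -1, drop = FALSE]
  .ct_trajectory(times, .ct_collapse_states(p, cc), "numeric")
}

#' Total drug mass along a trajectory
#'
#' @param traj a `ct_trajectory`.
#' @param p the [twin_parameters()] used to produce it.
#' @return Numeric vector of total amounts (umol) per time point.
#' @export
total_mass <- function(traj, p) {
  p$v_m * traj$C_m + p$v_i * traj$C_i + p$v_c * traj$C_c
}

#' @export
plot.ct_trajectory <- function(x, ...) {
  graphics::matplot(x$time_min, cbind(x$C_m, x$C_i, x$C_c), type = "l", lty = 1,
                    col = c("purple", "darkgreen", "red"),
                    xlab = "time [min]", ylab = "concentration [umol/mL]", ...)
  graphics::legend("topright", c("media", "interstitium", "intracellular"),
                   col = c("purple", "darkgreen", "red"), lty = 1, bty = "n")
  invisible(x)
}

#' Conventional one-compartment clearance fit
#'
#' The comparator analysis: the whole chip is one well-mixed compartment
#' with mono-exponential depletion `C(t) = C0 exp(-CL_c t / V)`, fitted by
#' ordinary least squares on the log-transformed concentrations, so
#' `CL_c = -slope * V`.
#'
#' @param obs data frame with columns `time_min` and `conc_umol_per_ml`
#'   (all concentrations > 0), or two numeric vectors via `times`/`conc`.
#' @param v_ml compartment volume (mL).
#' @return List with `cl_c_ml_min`, `c0` (back-transformed intercept),
#'   `slope_per_min`, `half_life_min` and the fitted `lm` object.
#' @export
fit_one_compartment <- function(obs, v_ml) {
  stopifnot(is.data.frame(obs), all(c("time_min", "conc_umol_per_ml") %in% names(obs)))
  if (nrow(obs) < 2L) stop("at least 2 time points are required", call. = FALSE)
  if (any(obs$conc_umol_per_ml <= 0))
    stop("all concentrations must be > 0 for the log-linear fit", call. = FALSE)
  fit <- stats::lm(log(conc_umol_per_ml) ~ time_min, data = obs)
  slope <- unname(stats::coef(fit)[2])
  cl <- -slope * v_ml
  list(cl_c_ml_min = cl, c0 = exp(unname(stats::coef(fit)[1])),
       slope_per_min = slope,
       half_life_min = if (cl > 0) log(2) * v_ml / cl else Inf,
       fit = fit)
}
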