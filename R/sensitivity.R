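#' Sensitivity model context for the chip model
#'
#' Wraps the three-compartment model as a scalar function of the nine input
#' parameters varied in sensitivity analysis: `K_int_med`, `P_endothelial`,
#' `SA_med_int_liver`, `K_water_int`, `K_water_cell`, `PA_cell_int`,
#' `PA_int_cell`, `fu` and `CL_c`. The output functional is the area under
#' the intracellular concentration curve over the observation window
#' (`output = "auc"`, the quantity the Kp_uu anchor consumes) or the
#' intracellular concentration at the end of the window
#' (`output = "final"`).
#'
#' Partition coefficients and cell-membrane permeability-area products take
#' their calculated (QSPR) baselines from the compound; the two parameters
#' whose status is "estimated" in the model - the endothelial permeability
#' and the intrinsic clearance - are supplied explicitly. Fitted liver-chip
#' twins typically sit in the uptake-limited regime where the endothelial
#' barrier is orders of magnitude tighter than a single cell membrane
#' (measured endothelial monolayers: ~1e-6 to 1e-5 cm/s), which is why
#' `p_endothelial` defaults to 1e-4 cm/min rather than the lipophilicity
#' QSPR value.
#'
#' @param chip a [chip_spec()].
#' @param compound a [compound_record()] giving the baseline partition and
#'   permeability parameters.
#' @param cl_c baseline intrinsic clearance (mL/min).
#' @param p_endothelial baseline endothelial permeability (cm/min);
#'   `NULL` falls back to the QSPR value of [compute_permeabilities()].
#' @param c0 initial media concentration (umol/mL).
#' @param t_end end of the observation window (min).
#' @param n_grid number of time-grid points.
#' @param output output functional, `"auc"` or `"final"`.
#' @return List with the model function `fn` (mapping a named 9-parameter
#'   vector to the scalar output), the `baseline` parameter vector, and the
#'   window description.
#' @export
ct_sensitivity_model <- function(chip, compound, cl_c, p_endothelial = 1e-4,
                                 c0 = 1, t_end = 360,
                                 n_grid = 101, output = c("auc", "final")) {
  output <- match.arg(output)
  validate_chip_spec(chip)
  pp <- compound_parameter_set(compound, chip)
  if (!is.null(p_endothelial)) pp$P_endothelial <- p_endothelial
  baseline <- c(K_int_med = pp$K_int_med, P_endothelial = pp$P_endothelial,
                SA_med_int_liver = chip$sa_med_int_liver_cm2,
                K_water_int = pp$K_water_int, K_water_cell = pp$K_water_cell,
                PA_cell_int = pp$PA_cell_int, PA_int_cell = pp$PA_int_cell,
                fu = compound$fu_media, CL_c = cl_c)
  times <- ct_auc_grid(t_end, n_grid)
  fn <- function(p) {
    p <- p[names(baseline)]
    k1 <- p[["fu"]] * p[["P_endothelial"]] * p[["SA_med_int_liver"]]
    params <- twin_parameters(
      k1 = k1, k2 = k1 / p[["K_int_med"]],
      k3 = p[["K_water_int"]] * p[["PA_int_cell"]],
      k4 = p[["K_water_cell"]] * p[["PA_cell_int"]],
      cl_c = p[["CL_c"]],
      v_m = chip$media_volume_ml, v_i = chip$v_interstitium_ml,
      v_c = chip$v_intracellular_ml,
      fu_media = p[["fu"]],
      n_media_chambers = chip$n_media_chambers,
      q_mix_ml_min = chip$q_mix_ml_min)
    traj <- suppressMessages(solve_analytic(params, c0 = c0, times = times))
    if (output == "auc") pracma::trapz(traj$time_min, traj$C_c)
    else traj$C_c[length(times)]
  }
  list(fn = fn, baseline = baseline, t_end = t_end, output = output)
}

#' Local (one-at-a-time) normalised sensitivity indices
#'
#' Perturbs each parameter by a fixed fraction (default +10%) one at a time
#' and returns the normalised index
#' `S_i = (dY/dP_i) * (P_i / Y)`, approximated by the forward difference
#' `(f(P_i (1+h)) - f(P)) / (h * f(P))`. Signs are preserved: a negative
#' index means the output falls when the parameter rises. A central
#' difference is available for smoother estimates.
#'
#' @param fn scalar model function of a named parameter vector (e.g. the
#'   `fn` of [ct_sensitivity_model()]).
#' @param p0 named baseline parameter vector.
#' @param perturbation relative step `h` (default 0.1, i.e. 10%).
#' @param scheme `"forward"` (default) or `"central"`.
#' @return Named numeric vector of sensitivity indices.
#' @export
local_sensitivity <- function(fn, p0, perturbation = 0.1,
                              scheme = c("forward", "central")) {
  scheme <- match.arg(scheme)
  y0 <- fn(p0)
  if (!is.finite(y0) || y0 == 0) stop("baseline output must be finite and non-zero", call. = FALSE)
  vapply(names(p0), function(nm) {
    up <- p0; up[[nm]] <- up[[nm]] * (1 + perturbation)
    if (scheme == "forward") {
      (fn(up) - y0) / (perturbation * y0)
    } else {
      dn <- p0; dn[[nm]] <- dn[[nm]] * (1 - perturbation)
      (fn(up) - fn(dn)) / (2 * perturbation * y0)
    }
  }, 0)
}

#' Variance-based (Sobol) sensitivity indices
#'
#' Monte Carlo estimation of first-order and total-order Sobol indices with
#' the radial (A/B/AB_i) sampling scheme: two independent uniform sample
#' matrices `A` and `B` of `n_base` rows are drawn within the bounds (as
#' seeded Latin hypercube samples, which stratify each marginal and reduce
#' estimator variance) and each parameter column of `A` is replaced in turn
#' by the corresponding column of `B`, giving `n_base * (k + 2)` model
#' evaluations. First-order indices use the Saltelli-2010 estimator
#' `S_i = mean(f(B) (f(AB_i) - f(A))) / V`, total-order indices the Jansen
#' estimator `T_i = mean((f(A) - f(AB_i))^2) / (2 V)`. Confidence intervals
#' come from bootstrap resampling of the base sample.
#'
#' @param fn scalar model function of a named parameter vector.
#' @param lower,upper named bounds of the uniform input distributions.
#' @param n_base base sample size; must be a power of 2 (balanced sampling
#'   design); a value below 64 is accepted with a recorded warning.
#' @param seed integer seed.
#' @param n_boot bootstrap resamples for the confidence intervals.
#' @param conf confidence level.
#' @return Object of class `ct_sobol`: a data frame `indices` with columns
#'   `parameter`, `first`, `first_lo`, `first_hi`, `total`, `total_lo`,
#'   `total_hi`, plus `n_samples`, `seed` and any recorded `warnings`.
#' @export
sobol_indices <- function(fn, lower, upper, n_base = 1024, seed = 1,
                          n_boot = 100, conf = 0.95) {
  stopifnot(length(lower) == length(upper), all(upper > lower))
  k <- length(lower)
  if (n_base < 2 || bitwAnd(n_base, n_base - 1L) != 0)
    stop("n_base must be a power of 2", call. = FALSE)
  warnings <- character()
  if (n_base < 64) warnings <- c(warnings, sprintf("n_base = %d is small (< 64); indices will be noisy", n_base))
  nms <- names(lower)
  set.seed(seed)
  draw <- function() {
    m <- lhs::randomLHS(n_base, k)
    sweep(sweep(m, 2, upper - lower, `*`), 2, lower, `+`)
  }
  a <- draw(); b <- draw()
  colnames(a) <- colnames(b) <- nms
  evals <- function(m) apply(m, 1, function(r) fn(stats::setNames(r, nms)))
  fa <- evals(a); fb <- evals(b)
  fab <- matrix(NA_real_, n_base, k, dimnames = list(NULL, nms))
  for (j in seq_len(k)) {
    abj <- a; abj[, j] <- b[, j]
    fab[, j] <- evals(abj)
  }
  est <- function(idx) {
    v <- stats::var(c(fa[idx], fb[idx]))
    first <- colMeans(fb[idx] * (fab[idx, , drop = FALSE] - fa[idx])) / v
    total <- colMeans((fa[idx] - fab[idx, , drop = FALSE])^2) / (2 * v)
    rbind(first, total)
  }
  point <- est(seq_len(n_base))
  boot <- array(NA_real_, c(2, k, n_boot))
  for (bnum in seq_len(n_boot))
    boot[, , bnum] <- est(sample.int(n_base, n_base, replace = TRUE))
  alpha <- (1 - conf) / 2
  qs <- apply(boot, c(1, 2), stats::quantile, probs = c(alpha, 1 - alpha))
  se <- apply(boot, c(1, 2), stats::sd)
  indices <- data.frame(parameter = nms,
                        first = point["first", ], first_lo = qs[1, 1, ], first_hi = qs[2, 1, ],
                        first_se = se[1, ],
                        total = point["total", ], total_lo = qs[1, 2, ], total_hi = qs[2, 2, ],
                        total_se = se[2, ], row.names = NULL)
  structure(list(indices = indices, n_samples = n_base,
                 n_evaluations = n_base * (k + 2), seed = seed,
                 warnings = warnings),
            class = "ct_sobol")
}

#' @export
print.ct_sobol <- function(x, ...) {
  cat(sprintf("<ct_sobol> n_base = %d (%d model evaluations), seed = %d\n",
              x$n_samples, x$n_evaluations, x$seed))
  print(x$indices[, c("parameter", "first", "total")], digits = 3)
  for (w in x$warnings) cat("warning:", w, "\n")
  invisible(x)
}

#' Sobol sensitivity of the chip model
#'
#' Global sensitivity of the intracellular-concentration output to the nine
#' model input parameters, sampled uniformly between fold-change bounds
#' around the baseline (default 0.1-fold to 10-fold).
#'
#' @param model a [ct_sensitivity_model()] context.
#' @param n_base base sample size (power of 2).
#' @param bounds_fold lower/upper multiplicative bounds on each parameter.
#' @param seed integer seed.
#' @param n_boot bootstrap resamples.
#' @return A `ct_sobol` object (see [sobol_indices()]).
#' @export
sobol_sensitivity <- function(model, n_base = 1024, bounds_fold = c(0.1, 10),
                              seed = 1, n_boot = 100) {
  stopifnot(is.list(model), is.function(model$fn), is.numeric(model$baseline))
  sobol_indices(model$fn,
                lower = model$baseline * bounds_fold[1],
                upper = model$baseline * bounds_fold[2],
                n_base = n_base, seed = seed, n_boot = n_boot)
}

#' Combined sensitivity report
#'
#' Runs the local one-at-a-time analysis and the Sobol analysis on the same
#' model context and writes (optionally) a tidy CSV.
#'
#' @param model a [ct_sensitivity_model()] context.
#' @param perturbation local perturbation fraction.
#' @param n_base,seed,n_boot Sobol settings; see [sobol_sensitivity()].
#' @param path optional CSV output path.
#' @return Data frame with one row per parameter: `local_s`, `sobol_first`
#'   (+ CI), `sobol_total` (+ CI).
#' @export
sensitivity_report <- function(model, perturbation = 0.1, n_base = 1024,
                               seed = 1, n_boot = 100, path = NULL) {
  local_s <- local_sensitivity(model$fn, model$baseline, perturbation)
  sob <- sobol_sensitivity(model, n_base = n_base, seed = seed, n_boot = n_boot)
  out <- cbind(data.frame(parameter = names(local_s), local_s = unname(local_s)),
               sob$indices[match(names(local_s), sob$indices$parameter), -1])
  rownames(out) <- NULL
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}

#' Bar chart of sensitivity indices
#'
#' @param report a [sensitivity_report()] data frame.
#' @param which `"local"` or `"sobol"`.
#' @export
plot_sensitivity <- function(report, which = c("sobol", "local")) {
  which <- match.arg(which)
  if (which == "local") {
    graphics::barplot(report$local_s, names.arg = report$parameter, las = 2,
                      col = ifelse(report$local_s >= 0, "steelblue", "firebrick"),
                      ylab = "normalised local sensitivity")
  } else {
    m <- t(as.matrix(report[, c("first", "total")]))
    graphics::barplot(m, beside = TRUE, names.arg = report$parameter, las = 2,
                      col = c("steelblue", "orange"), ylab = "Sobol index")
    graphics::legend("topright", c("first-order", "total-order"),
                     fill = c("steelblue", "orange"), bty = "n")
  }
  invisible(report)
}
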