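#' Weighted residual cost
#'
#' The objective minimised during clearance estimation: the sum over
#' observation times of squared relative residuals
#' `((obs - pred)/pred)^2`, plus, when an observed unbound
#' intracellular-to-media partition coefficient is supplied, the squared
#' relative deviation of the Kp_uu anchor,
#' `weight * ((Kpuu_obs - Kpuu_pred)/Kpuu_pred)^2`. Relative weighting makes
#' early high and late low concentrations count equally on depletion curves
#' spanning orders of magnitude.
#'
#' @param obs,pred numeric vectors of observed and predicted media
#'   concentrations at the same times.
#' @param kpuu_obs,kpuu_pred optional observed and model-predicted Kp_uu
#'   values for the anchor term.
#' @param anchor_weight weight of the anchor term (default 1: plain
#'   addition).
#' @param penalty large finite value returned (never `NaN`) when any
#'   prediction is non-positive or non-finite; such evaluations are flagged
#'   via the `"penalised"` attribute.
#' @return Non-negative scalar cost.
#' @export
cost_function <- function(obs, pred, kpuu_obs = NULL, kpuu_pred = NULL,
                          anchor_weight = 1, penalty = 1e8) {
  stopifnot(length(obs) == length(pred))
  if (any(!is.finite(pred)) || any(pred <= 0))
    return(structure(penalty, penalised = TRUE))
  ssq <- sum(((obs - pred) / pred)^2)
  if (!is.null(kpuu_obs)) {
    if (is.null(kpuu_pred) || !is.finite(kpuu_pred) || kpuu_pred <= 0)
      return(structure(penalty, penalised = TRUE))
    ssq <- ssq + anchor_weight * ((kpuu_obs - kpuu_pred) / kpuu_pred)^2
  }
  ssq
}

#' Graded time grid for AUC integration
#'
#' Time grid refined near `t = 0` (points placed as `t_max * u^power` for
#' `u` uniform on the unit interval). The interstitial and intracellular
#' compartments are orders of magnitude smaller than the media chamber, so
#' their concentrations equilibrate in a fast initial boundary layer that a
#' uniform grid under-resolves; the graded grid keeps trapezoidal AUCs (and
#' hence Kp_uu predictions) accurate without extra model evaluations.
#'
#' @param t_max end of the window (min).
#' @param n number of grid points.
#' @param power grading exponent; 1 recovers a uniform grid.
#' @return Increasing numeric vector from 0 to `t_max`.
#' @export
ct_auc_grid <- function(t_max, n = 101, power = 3) {
  stopifnot(t_max > 0, n >= 2)
  t_max * seq(0, 1, length.out = n)^power
}

#' Predicted unbound intracellular-to-media partition coefficient
#'
#' `Kpuu_pred = AUC(C_i + C_c) / AUC(C_m) * fu_cell / fu_media`, with areas
#' under the simulated curves computed by the trapezoidal rule on the
#' trajectory grid. This links the (usually unobserved) intracellular
#' kinetics to the media depletion curve.
#'
#' @param traj a `ct_trajectory` covering the observation window.
#' @param fu_cell unbound intracellular fraction (e.g. [qsar_fu_cell()]).
#' @param fu_media unbound fraction in media.
#' @return Dimensionless Kp_uu prediction.
#' @export
predict_kpuu <- function(traj, fu_cell, fu_media) {
  stopifnot(inherits(traj, "ct_trajectory"))
  auc_m <- pracma::trapz(traj$time_min, traj$C_m)
  if (auc_m <= 0) stop("media AUC is zero; cannot form Kp_uu", call. = FALSE)
  auc_tissue <- pracma::trapz(traj$time_min, traj$C_i + traj$C_c)
  (auc_tissue / auc_m) * (fu_cell / fu_media)
}

#' Compound-specific scaling factor
#'
#' Ratio of observed to model-predicted Kp_uu, `SF = Kpuu_obs / Kpuu_pred`,
#' used to scale the predicted human clearance of the compound.
#'
#' @param kpuu_obs,kpuu_pred observed and predicted Kp_uu, both > 0.
#' @return Dimensionless scaling factor.
#' @export
scaling_factor <- function(kpuu_obs, kpuu_pred) {
  if (!is.finite(kpuu_obs) || kpuu_obs <= 0 || !is.finite(kpuu_pred) || kpuu_pred <= 0)
    stop("kpuu_obs and kpuu_pred must be > 0", call. = FALSE)
  kpuu_obs / kpuu_pred
}

#' Fitting options
#'
#' @param n_starts number of seeded multi-starts of the Nelder-Mead search.
#' @param seed integer seed controlling the start points.
#' @param maxit,reltol Nelder-Mead iteration cap and relative tolerance.
#' @param anchor `"auto"` uses the observed Kp_uu when supplied and
#'   otherwise scans the candidate grid; `"observed"`, `"grid"` and
#'   `"none"` force the respective behaviour.
#' @param kpuu_obs observed Kp_uu (when available).
#' @param anchor_weight weight of the anchor residual.
#' @param c0 initial media concentration; defaults to the observation at
#'   t = 0.
#' @param cl_c_range search range for CL_c starts (mL/min, log-uniform).
#' @param sa_fold_range multiplicative range around the nominal surface
#'   area (and nominal endothelial permeability) for their starts.
#' @param partition_method partition-coefficient method.
#' @param n_auc_grid number of grid points for the Kp_uu AUC integration.
#' @param cv_flag coefficient of variation of `CL_c` across starts above
#'   which the identifiability warning is raised.
#' @return Named list of options.
#' @export
ct_fit_options <- function(n_starts = 5, seed = 1, maxit = 2000, reltol = 1e-8,
                           anchor = c("auto", "observed", "grid", "none"),
                           kpuu_obs = NULL, anchor_weight = 1, c0 = NULL,
                           cl_c_range = c(1e-4, 10), sa_fold_range = c(0.1, 10),
                           partition_method = "poulin_theil",
                           n_auc_grid = 101, cv_flag = 0.2) {
  list(n_starts = n_starts, seed = as.integer(seed), maxit = maxit,
       reltol = reltol, anchor = match.arg(anchor), kpuu_obs = kpuu_obs,
       anchor_weight = anchor_weight, c0 = c0, cl_c_range = cl_c_range,
       sa_fold_range = sa_fold_range, partition_method = partition_method,
       n_auc_grid = n_auc_grid, cv_flag = cv_flag)
}

# mean observed concentration per time (collapses replicates)
.ct_aggregate_obs <- function(obs) {
  stopifnot(is.data.frame(obs), all(c("time_min", "conc_umol_per_ml") %in% names(obs)))
  agg <- stats::aggregate(conc_umol_per_ml ~ time_min, data = obs, FUN = mean)
  agg[order(agg$time_min), ]
}

#' Estimate on-chip clearance with the digital twin
#'
#' Fits the three-compartment model to an observed media depletion series by
#' Nelder-Mead minimisation of [cost_function()]. Free parameters (by
#' default the intrinsic clearance and the media/interstitium exchange
#' area) are optimised on the log scale to enforce positivity, from several
#' seeded random starts; the best start is returned together with the
#' spread of the clearance estimate across starts, which flags practical
#' non-identifiability (e.g. permeability-limited depletion where uptake
#' and clearance trade off).
#'
#' @param obs data frame with columns `time_min`, `conc_umol_per_ml`
#'   (optional `replicate`, averaged per time point); at least 3 points.
#' @param chip a [chip_spec()].
#' @param compound a [compound_record()].
#' @param free_params subset of `c("CL_c", "SA_med_int_liver",
#'   "P_endothelial")`.
#' @param options a [ct_fit_options()] list.
#' @return Object of class `estimation_result`: the fitted clearance
#'   `cl_c_hat` (mL/min), co-estimated `sa_hat` / `p_endothelial_hat`, final
#'   objective `ssq`, `kpuu_pred`, `kpuu_obs`, scaling factor `sf`,
#'   convergence information, the per-start table and the identifiability
#'   flag.
#' @export
fit_twin <- function(obs, chip, compound,
                     free_params = c("CL_c", "SA_med_int_liver"),
                     options = ct_fit_options()) {
  validate_chip_spec(chip, require_complete = FALSE)
  stopifnot(inherits(compound, "compound_record"))
  allowed <- c("CL_c", "SA_med_int_liver", "P_endothelial")
  if (!length(free_params) || !all(free_params %in% allowed))
    stop("free_params must be a non-empty subset of: ", paste(allowed, collapse = ", "), call. = FALSE)
  agg <- .ct_aggregate_obs(obs)
  if (nrow(agg) < 3L) stop("at least 3 observation times are required", call. = FALSE)
  c0 <- options$c0
  if (is.null(c0)) {
    if (min(agg$time_min) > 0)
      stop("no t = 0 observation; supply the initial concentration via ct_fit_options(c0 = )", call. = FALSE)
    c0 <- agg$conc_umol_per_ml[agg$time_min == 0][1]
  }
  obs_t <- agg$time_min
  obs_c <- agg$conc_umol_per_ml
  pp0 <- compound_parameter_set(compound, chip, method = options$partition_method)
  fu_cell <- pp0$fu_cell
  sa_nom <- chip$sa_med_int_liver_cm2
  if (!is.finite(sa_nom) || sa_nom <= 0) {
    if (!"SA_med_int_liver" %in% free_params)
      stop("SA_med_int_liver is unresolved for this chip; include it in free_params or set it on the chip", call. = FALSE)
    sa_nom <- max(chip$cell_number, 1) * .ct_constants$cell_geometry[["footprint_cm2"]]
  }
  grid_t <- sort(unique(c(ct_auc_grid(max(obs_t), options$n_auc_grid), obs_t)))
  idx_obs <- match(obs_t, grid_t)

  eval_candidate <- function(theta, kpuu_obs_eff) {
    sa <- if ("SA_med_int_liver" %in% free_params) theta[["SA_med_int_liver"]] else sa_nom
    pp <- pp0
    if ("P_endothelial" %in% free_params) pp$P_endothelial <- theta[["P_endothelial"]]
    params <- tryCatch(
      build_rate_constants(pp, chip, fu_media = compound$fu_media,
                           cl_c = theta[["CL_c"]], sa_med_int_liver_cm2 = sa),
      error = function(e) NULL)
    if (is.null(params)) return(list(cost = structure(1e8, penalised = TRUE)))
    traj <- tryCatch(suppressMessages(solve_analytic(params, c0 = c0, times = grid_t)),
                     error = function(e) NULL)
    if (is.null(traj)) return(list(cost = structure(1e8, penalised = TRUE)))
    kpuu_pred <- tryCatch(predict_kpuu(traj, fu_cell, compound$fu_media),
                          error = function(e) NA_real_)
    cost <- cost_function(obs_c, traj$C_m[idx_obs],
                          kpuu_obs = kpuu_obs_eff, kpuu_pred = kpuu_pred,
                          anchor_weight = options$anchor_weight)
    list(cost = cost, kpuu_pred = kpuu_pred, params = params)
  }

  fixed_cl <- !"CL_c" %in% free_params
  theta_names <- free_params
  make_obj <- function(kpuu_obs_eff) function(lpar) {
    theta <- stats::setNames(exp(lpar), theta_names)
    if (fixed_cl) theta[["CL_c"]] <- 0
    as.numeric(eval_candidate(theta, kpuu_obs_eff)$cost)
  }

  run_starts <- function(kpuu_obs_eff) {
    set.seed(options$seed)
    n <- options$n_starts
    starts <- matrix(NA_real_, n, length(theta_names),
                     dimnames = list(NULL, theta_names))
    if ("CL_c" %in% theta_names)
      starts[, "CL_c"] <- exp(stats::runif(n, log(options$cl_c_range[1]), log(options$cl_c_range[2])))
    if ("SA_med_int_liver" %in% theta_names)
      starts[, "SA_med_int_liver"] <- sa_nom * exp(stats::runif(n, log(options$sa_fold_range[1]), log(options$sa_fold_range[2])))
    if ("P_endothelial" %in% theta_names)
      starts[, "P_endothelial"] <- pp0$P_endothelial * exp(stats::runif(n, log(options$sa_fold_range[1]), log(options$sa_fold_range[2])))
    obj <- make_obj(kpuu_obs_eff)
    res <- vector("list", n)
    for (i in seq_len(n)) {
      lpar <- log(starts[i, ])
      fit <- tryCatch({
        if (length(lpar) == 1L)
          stats::optim(lpar, obj, method = "Brent",
                       lower = lpar - log(1e6), upper = lpar + log(1e6),
                       control = list(maxit = options$maxit))
        else
          stats::optim(lpar, obj, method = "Nelder-Mead",
                       control = list(maxit = options$maxit, reltol = options$reltol))
      }, error = function(e) e)
      res[[i]] <- if (inherits(fit, "error")) {
        list(ok = FALSE, message = conditionMessage(fit), start = starts[i, ])
      } else {
        list(ok = TRUE, par = stats::setNames(exp(fit$par), theta_names),
             value = fit$value, initial = obj(lpar),
             convergence = fit$convergence,
             counts = unname(fit$counts[1]), start = starts[i, ])
      }
    }
    res
  }

  # resolve the anchor mode
  anchor <- options$anchor
  kpuu_obs <- options$kpuu_obs
  if (anchor == "auto") anchor <- if (!is.null(kpuu_obs)) "observed" else "grid"
  if (anchor == "observed" && is.null(kpuu_obs))
    stop("anchor = 'observed' requires ct_fit_options(kpuu_obs = )", call. = FALSE)

  kpuu_grid_used <- NULL
  if (anchor == "grid") {
    fac <- .ct_constants$kpuu_ionisation_factor[[as.character(compound$ionisation)]]
    grid_vals <- .ct_constants$kpuu_grid * fac
    per_grid <- lapply(grid_vals, run_starts)
    best_costs <- vapply(per_grid, function(rs)
      min(vapply(rs, function(r) if (isTRUE(r$ok)) r$value else Inf, 0)), 0)
    kpuu_grid_used <- data.frame(kpuu_obs = grid_vals, best_cost = best_costs)
    pick <- which.min(best_costs)
    starts_res <- per_grid[[pick]]
    kpuu_obs_eff <- grid_vals[pick]
    kpuu_source <- "grid"
  } else {
    kpuu_obs_eff <- if (anchor == "observed") kpuu_obs else NULL
    starts_res <- run_starts(kpuu_obs_eff)
    kpuu_source <- if (anchor == "observed") "observed" else "none"
  }

  ok <- vapply(starts_res, function(r) isTRUE(r$ok), TRUE)
  if (!any(ok)) {
    msgs <- vapply(starts_res, function(r) r$message %||% "unknown", "")
    stop("all optimisation starts failed:\n", paste(sprintf("  start %d: %s", seq_along(msgs), msgs), collapse = "\n"), call. = FALSE)
  }
  vals <- vapply(starts_res, function(r) if (isTRUE(r$ok)) r$value else Inf, 0)
  best <- starts_res[[which.min(vals)]]
  theta_hat <- best$par
  if (fixed_cl) theta_hat[["CL_c"]] <- 0
  final <- eval_candidate(theta_hat, kpuu_obs_eff)

  # identifiability diagnostic: spread of CL_c across starts that reached the
  # optimal cost plateau (a flat ridge yields equal costs at different CL_c)
  near_opt <- ok & vals <= min(vals) * 2 + 1e-10
  cl_starts <- vapply(starts_res[near_opt], function(r)
    if ("CL_c" %in% theta_names) r$par[["CL_c"]] else NA_real_, 0)
  cl_cv <- if (length(cl_starts) && all(is.finite(cl_starts)) && mean(cl_starts) > 0)
    stats::sd(cl_starts) / mean(cl_starts) else NA_real_
  if (length(cl_starts) == 1L) cl_cv <- 0

  starts_tab <- do.call(rbind, lapply(seq_along(starts_res), function(i) {
    r <- starts_res[[i]]
    data.frame(start = i, ok = isTRUE(r$ok),
               cl_c = if (isTRUE(r$ok) && "CL_c" %in% theta_names) r$par[["CL_c"]] else NA_real_,
               cost = if (isTRUE(r$ok)) r$value else NA_real_,
               initial_cost = if (isTRUE(r$ok)) r$initial else NA_real_,
               convergence = if (isTRUE(r$ok)) r$convergence else NA_integer_)
  }))

  structure(list(
    cl_c_hat = if ("CL_c" %in% theta_names) theta_hat[["CL_c"]] else 0,
    sa_hat = if ("SA_med_int_liver" %in% theta_names) theta_hat[["SA_med_int_liver"]] else sa_nom,
    p_endothelial_hat = if ("P_endothelial" %in% theta_names) theta_hat[["P_endothelial"]] else pp0$P_endothelial,
    ssq = best$value,
    ssq_initial = best$initial,
    kpuu_pred = final$kpuu_pred,
    kpuu_obs = kpuu_obs_eff,
    kpuu_source = kpuu_source,
    kpuu_grid = kpuu_grid_used,
    sf = if (!is.null(kpuu_obs_eff) && is.finite(final$kpuu_pred) && final$kpuu_pred > 0)
      scaling_factor(kpuu_obs_eff, final$kpuu_pred) else NA_real_,
    converged = identical(best$convergence, 0L) || identical(best$convergence, 0),
    n_iter = best$counts,
    starts = starts_tab,
    cl_c_cv_starts = cl_cv,
    identifiability_warning = is.finite(cl_cv) && cl_cv > options$cv_flag,
    free_params = free_params,
    fu_cell = fu_cell,
    c0 = c0,
    seed = options$seed,
    options = options
  ), class = "estimation_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.estimation_result <- function(x, ...) {
  cat("<estimation_result>\n")
  cat(sprintf("  CL_c = %.4g mL/min   SA = %.4g cm2   ssq = %.4g\n",
              x$cl_c_hat, x$sa_hat, x$ssq))
  cat(sprintf("  Kp_uu pred = %.4g (anchor: %s%s)   SF = %.4g\n", x$kpuu_pred,
              x$kpuu_source,
              if (!is.null(x$kpuu_obs)) sprintf(", obs = %.3g", x$kpuu_obs) else "",
              x$sf))
  cat(sprintf("  converged: %s after %d evaluations; CL_c CV across starts %.2g%s\n",
              x$converged, x$n_iter, x$cl_c_cv_starts,
              if (isTRUE(x$identifiability_warning)) "  [identifiability warning]" else ""))
  invisible(x)
}

#' Write a fit report as JSON
#'
#' Serialises an [fit_twin()] result, including the full option set and
#' seed, for an auditable record of the estimation run.
#'
#' @param result an `estimation_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(result, path) {
  stopifnot(inherits(result, "estimation_result"))
  out <- unclass(result)
  out$options$c0 <- result$c0
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null", pretty = TRUE,
                       force = TRUE)
  invisible(path)
}
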