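#' Human scaling constants
#'
#' Physiological constants of the in vitro-to-in vivo extrapolation:
#' hepatocellularity `hc` (cells per gram of liver, default 120 million),
#' liver weight `lw` (grams per kg body weight, default 25.7) and hepatic
#' blood flow `q_h` (mL/min/kg, default 20.7). All overridable.
#'
#' @param hc hepatocellularity, cells/g liver.
#' @param lw liver weight, g/kg body weight.
#' @param q_h hepatic blood flow, mL/min/kg.
#' @return Object of class `human_scaling_constants`.
#' @export
human_scaling_constants <- function(hc = 120e6, lw = 25.7, q_h = 20.7) {
  vals <- c(hc = hc, lw = lw, q_h = q_h)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all scaling constants must be > 0", call. = FALSE)
  structure(as.list(vals), class = "human_scaling_constants")
}

#' Scale on-chip clearance to human unbound intrinsic clearance
#'
#' Hepatocellularity scale-up of an on-chip intrinsic clearance to a
#' whole-liver human equivalent:
#' `CL_int_u_H = (CL_chip / cell_number) * HC * LW / fu_inc * SF`
#' (mL/min/kg). The per-cell clearance is multiplied by the number of
#' hepatocytes per kilogram of body weight (`HC * LW`), corrected for
#' binding in the incubation (`fu_inc`) and by the compound-specific
#' scaling factor `SF` (see [scaling_factor()]).
#'
#' For clearances estimated with the digital twin, media binding is already
#' inside the uptake rate `k1`, so `fu_inc = 1` avoids double counting; for
#' conventional one-compartment clearances, supply the measured incubation
#' unbound fraction.
#'
#' @param cl_chip on-chip clearance (mL/min), > 0.
#' @param cell_number hepatocytes on the chip, > 0.
#' @param fu_inc unbound fraction in the incubation, in (0, 1].
#' @param sf compound-specific scaling factor (default 1).
#' @param k a [human_scaling_constants()] object.
#' @return Unbound intrinsic human clearance, mL/min/kg.
#' @export
scale_to_human <- function(cl_chip, cell_number, fu_inc = 1, sf = 1,
                           k = human_scaling_constants()) {
  stopifnot(inherits(k, "human_scaling_constants"))
  vals <- c(cl_chip, cell_number, fu_inc, sf)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("cl_chip, cell_number, fu_inc and sf must all be > 0", call. = FALSE)
  (cl_chip / cell_number) * k$hc * k$lw / fu_inc * sf
}

#' Well-stirred liver model
#'
#' Predicted hepatic blood clearance
#' `CL_H = Q_H * fu_b * CL_int_u_H / (Q_H + fu_b * CL_int_u_H)`: bounded
#' above by the hepatic blood flow (flow-limited asymptote) and equal to
#' `fu_b * CL_int_u_H` in the clearance-limited limit.
#'
#' @param cl_int_u_h unbound intrinsic human clearance (mL/min/kg), >= 0.
#' @param fu_b fraction unbound in blood, in (0, 1].
#' @param k a [human_scaling_constants()] object.
#' @return Predicted hepatic clearance, mL/min/kg, strictly below `q_h`.
#' @export
well_stirred <- function(cl_int_u_h, fu_b, k = human_scaling_constants()) {
  stopifnot(inherits(k, "human_scaling_constants"))
  if (!is.finite(cl_int_u_h) || cl_int_u_h < 0) stop("cl_int_u_h must be >= 0", call. = FALSE)
  if (!is.finite(fu_b) || fu_b <= 0 || fu_b > 1) stop("fu_b must lie in (0, 1]", call. = FALSE)
  k$q_h * fu_b * cl_int_u_h / (k$q_h + fu_b * cl_int_u_h)
}

#' Fraction unbound in blood
#'
#' `fu_b = fu_p / Rbp` from the plasma (or media) unbound fraction and the
#' blood-to-plasma ratio, capped at 1 (a fraction unbound cannot exceed
#' unity, which the raw quotient can for weakly partitioning compounds with
#' `Rbp < fu_p`); a directly measured `fu_blood` takes precedence when
#' supplied.
#'
#' @param fu_p fraction unbound in plasma/media, in (0, 1].
#' @param rbp blood-to-plasma concentration ratio, > 0.
#' @param fu_blood optional measured fraction unbound in blood.
#' @return Fraction unbound in blood.
#' @export
fu_blood <- function(fu_p, rbp = 1, fu_blood = NULL) {
  if (!is.null(fu_blood)) {
    if (!is.finite(fu_blood) || fu_blood <= 0) stop("measured fu_blood must be > 0", call. = FALSE)
    return(fu_blood)
  }
  if (!is.finite(fu_p) || fu_p <= 0 || fu_p > 1) stop("fu_p must lie in (0, 1]", call. = FALSE)
  if (!is.finite(rbp) || rbp <= 0) stop("rbp must be > 0", call. = FALSE)
  min(fu_p / rbp, 1)
}

#' Average fold error of prediction ratios
#'
#' `AFE = 10^mean(log10(ratio))`: the geometric mean of predicted/observed
#' ratios; 1 indicates unbiased prediction, and `AFE(r) * AFE(1/r) = 1`.
#'
#' @param ratios vector of predicted/observed ratios, all > 0.
#' @return Scalar AFE.
#' @export
average_fold_error <- function(ratios) {
  if (any(!is.finite(ratios)) || any(ratios <= 0)) stop("ratios must be > 0", call. = FALSE)
  10^mean(log10(ratios))
}

#' Summarise prediction performance
#'
#' For a table of clearance predictions with observed values, computes per
#' method the mean, SD and CV of the predicted/observed ratios, the average
#' fold error, and the fractions of compounds within 1.5-fold and 3-fold of
#' unity, plus a kernel-density curve of the ratios for plotting.
#'
#' @param predictions data frame with columns `compound`,
#'   `cl_h_pred_ml_min_kg`, `cl_h_obs_ml_min_kg` and `method_tag`.
#' @return List with one element per method tag; each holds `n`,
#'   `mean_ratio`, `sd_ratio`, `cv_pct`, `afe`, `frac_within_1p5`,
#'   `frac_within_3`, the `ratios` and a `density` (x, y) curve.
#' @export
prediction_summary <- function(predictions) {
  stopifnot(is.data.frame(predictions),
            all(c("cl_h_pred_ml_min_kg", "cl_h_obs_ml_min_kg", "method_tag") %in% names(predictions)))
  ok <- is.finite(predictions$cl_h_obs_ml_min_kg) & predictions$cl_h_obs_ml_min_kg > 0
  if (!any(ok)) stop("no predictions with observed clearance values", call. = FALSE)
  predictions <- predictions[ok, ]
  out <- lapply(split(predictions, predictions$method_tag), function(df) {
    r <- df$cl_h_pred_ml_min_kg / df$cl_h_obs_ml_min_kg
    fold <- pmax(r, 1 / r)
    list(n = nrow(df),
         mean_ratio = mean(r), sd_ratio = stats::sd(r),
         cv_pct = if (mean(r) > 0 && nrow(df) > 1) 100 * stats::sd(r) / mean(r) else NA_real_,
         afe = average_fold_error(r),
         frac_within_1p5 = mean(fold <= 1.5),
         frac_within_3 = mean(fold <= 3),
         ratios = r,
         density = if (nrow(df) > 1) {
           d <- stats::density(r)
           list(x = d$x, y = d$y)
         })
  })
  structure(out, class = "ct_prediction_summary")
}

#' @export
print.ct_prediction_summary <- function(x, ...) {
  for (m in names(x)) {
    s <- x[[m]]
    cat(sprintf("%s (n = %d): mean ratio %.3f +/- %.3f (CV %.1f%%), AFE %.3f, %.0f%% within 1.5-fold, %.0f%% within 3-fold\n",
                m, s$n, s$mean_ratio, s$sd_ratio, s$cv_pct, s$afe,
                100 * s$frac_within_1p5, 100 * s$frac_within_3))
  }
  invisible(x)
}

#' End-to-end human clearance prediction for one compound
#'
#' Convenience chain: on-chip clearance -> hepatocellularity scale-up ->
#' well-stirred model, with blood binding from [fu_blood()].
#'
#' @param cl_chip on-chip clearance (mL/min).
#' @param chip a [chip_spec()] (supplies the cell number).
#' @param compound a [compound_record()] (supplies binding and Rbp).
#' @param fu_inc incubation unbound fraction used in the scale-up
#'   (default 1: digital-twin convention, binding already in `k1`).
#' @param sf compound-specific scaling factor.
#' @param method_tag label for the provenance of `cl_chip`
#'   (`"digital_twin"` or `"conventional"`).
#' @param k a [human_scaling_constants()] object.
#' @return One-row data frame with `compound`, `cl_int_u_h_ml_min_kg`,
#'   `cl_h_pred_ml_min_kg` and `method_tag`.
#' @export
predict_human_clearance <- function(cl_chip, chip, compound, fu_inc = 1,
                                    sf = 1, method_tag = "digital_twin",
                                    k = human_scaling_constants()) {
  validate_chip_spec(chip, require_complete = FALSE)
  stopifnot(inherits(compound, "compound_record"))
  cl_int <- scale_to_human(cl_chip, chip$cell_number, fu_inc = fu_inc, sf = sf, k = k)
  fb <- fu_blood(compound$fu_media, rbp = compound$rbp %||% 1,
                 fu_blood = compound$fu_blood)
  data.frame(compound = compound$name,
             cl_int_u_h_ml_min_kg = cl_int,
             cl_h_pred_ml_min_kg = well_stirred(cl_int, fb, k = k),
             method_tag = method_tag)
}
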