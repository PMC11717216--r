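#' Compound physicochemical record
#'
#' Minimal physicochemical identity of a compound: lipophilicity (logP),
#' molecular weight, fraction unbound in the culture media, ionisation class
#' at physiological pH (-1 anionic, 0 neutral, +1 cationic) and optional
#' blood binding information (blood-to-plasma ratio and/or measured fraction
#' unbound in blood). These three core descriptors drive all six downstream
#' partitioning and permeability parameters of the kinetic model.
#'
#' @param name compound identifier.
#' @param logp octanol:water log partition coefficient of the neutral form.
#' @param mw molecular weight (g/mol), > 0.
#' @param fu_media fraction unbound in the culture media, in (0, 1].
#' @param ionisation ionisation class, one of -1, 0, +1.
#' @param rbp optional blood-to-plasma concentration ratio (> 0).
#' @param fu_blood optional measured fraction unbound in blood; when present
#'   it takes precedence over `fu_media / rbp` in the IVIVE step.
#' @return Object of class `compound_record`.
#' @export
compound_record <- function(name, logp, mw, fu_media, ionisation = 0,
                            rbp = NULL, fu_blood = NULL) {
  stopifnot(is.numeric(logp), length(logp) == 1L, is.finite(logp))
  if (!is.numeric(mw) || length(mw) != 1L || !is.finite(mw) || mw <= 0)
    stop("mw must be a positive number (g/mol)", call. = FALSE)
  if (!is.numeric(fu_media) || fu_media <= 0 || fu_media > 1)
    stop("fu_media must lie in (0, 1]", call. = FALSE)
  if (!ionisation %in% c(-1, 0, 1))
    stop("ionisation must be one of -1, 0, +1", call. = FALSE)
  if (!is.null(rbp) && (!is.finite(rbp) || rbp <= 0))
    stop("rbp must be > 0 when given", call. = FALSE)
  if (!is.null(fu_blood) && (fu_blood <= 0 || fu_blood > 1))
    stop("fu_blood must lie in (0, 1] when given", call. = FALSE)
  structure(list(name = as.character(name), logp = logp, mw = mw,
                 fu_media = fu_media, ionisation = as.integer(ionisation),
                 rbp = rbp, fu_blood = fu_blood),
            class = "compound_record")
}

#' @export
print.compound_record <- function(x, ...) {
  cat(sprintf("<compound_record> %s: logP %.2f, MW %.0f g/mol, fu_media %.3g, ionisation %+d\n",
              x$name, x$logp, x$mw, x$fu_media, x$ionisation))
  invisible(x)
}

#' Read a compound table
#'
#' Reads a CSV with one compound per row (columns `name, logp, mw, fu_media,
#' ionisation`, optional `rbp`, `fu_blood`) into a list of
#' [compound_record()] objects.
#'
#' @param path CSV file path.
#' @return Named list of `compound_record`s.
#' @export
read_compound_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "logp", "mw", "fu_media", "ionisation")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("compound table missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i) {
    compound_record(df$name[i], df$logp[i], df$mw[i], df$fu_media[i],
                    df$ionisation[i],
                    rbp = if ("rbp" %in% names(df) && is.finite(df$rbp[i])) df$rbp[i],
                    fu_blood = if ("fu_blood" %in% names(df) && is.finite(df$fu_blood[i])) df$fu_blood[i])
  })
  names(out) <- df$name
  out
}

.ct_partition_methods <- c("poulin_theil", "pk_sim_standard", "rodgers_rowland",
                           "schmitt", "berezhkovskiy")

# Poulin-Theil tissue:water coefficient for one composition vector
.ct_pt_tissue_water <- function(p_ow, comp) {
  unname(comp[["water"]] +
           p_ow * (comp[["neutral_lipid"]] + 0.3 * comp[["phospholipid"]]) +
           0.7 * comp[["phospholipid"]])
}

#' Partition coefficients from compound physicochemistry
#'
#' Computes the three partition coefficients of the kinetic model from logP
#' (shifted by the ionisation-class offset) using the Poulin-Theil
#' tissue-composition equation
#' `K = V_w + P * (V_nl + 0.3 V_ph) + 0.7 V_ph`, with a plasma-like
#' composition for the interstitium and a hepatocyte-like composition for
#' the intracellular space. The media is taken as an aqueous reference
#' (media binding is carried separately by `fu_media` in the uptake rate),
#' so the media/interstitium coefficient equals the interstitium:water
#' coefficient.
#'
#' @param compound a [compound_record()].
#' @param method partition method; only `"poulin_theil"` is implemented, the
#'   other method slots of the interface raise a not-implemented error.
#' @return Named list with `K_int_med` (interstitium:media),
#'   `K_water_int` (interstitium:water) and `K_water_cell` (cell:water), all
#'   strictly positive and non-decreasing in logP.
#' @export
compute_partition_coefficients <- function(compound, method = "poulin_theil") {
  stopifnot(inherits(compound, "compound_record"))
  method <- match.arg(method, .ct_partition_methods)
  if (method != "poulin_theil")
    stop(sprintf("partition method '%s' is not implemented; available: poulin_theil", method),
         call. = FALSE)
  comp <- .ct_constants$tissue_composition
  p_ow <- 10^ct_effective_logp(compound$logp, compound$ionisation)
  k_int_water  <- .ct_pt_tissue_water(p_ow, comp$interstitium)
  k_cell_water <- .ct_pt_tissue_water(p_ow, comp$cell)
  list(K_int_med = k_int_water, K_water_int = k_int_water,
       K_water_cell = k_cell_water)
}

# intrinsic transcellular permeability QSPR with unstirred-layer cap (cm/min)
.ct_perm_qspr <- function(logp_eff, mw) {
  k <- .ct_constants$permeability
  p_int <- k$p_ref_cm_min * 10^(k$logp_slope * logp_eff) * (mw / k$mw_ref)^(-k$mw_exponent)
  k$p_max_cm_min * p_int / (k$p_max_cm_min + p_int)
}

#' Permeabilities and permeability-area products
#'
#' Transcellular permeability follows a QSPR that is log-linear in the
#' effective logP and an inverse power of molecular weight, saturating at an
#' unstirred-layer maximum. The endothelial barrier is modelled as a leakier
#' version of the same membrane plus a size-dependent paracellular floor.
#' Permeability-area products for the hepatocyte membrane use the total
#' membrane area of the seeded cells (per-cell area times cell number);
#' passive diffusion is symmetric, so both directions share one PA and the
#' directional asymmetry is carried by the partition coefficients.
#'
#' @param compound a [compound_record()].
#' @param chip a [chip_spec()] supplying the cell number.
#' @param sa_cell_cm2 optional override of the total cell-membrane area.
#' @return Named list with `P_endothelial` (cm/min), `PA_int_cell` and
#'   `PA_cell_int` (mL/min), and the membrane area used (`sa_cell_cm2`).
#' @export
compute_permeabilities <- function(compound, chip, sa_cell_cm2 = NULL) {
  stopifnot(inherits(compound, "compound_record"))
  if (!is.finite(compound$mw) || compound$mw <= 0)
    stop("mw must be positive", call. = FALSE)
  k <- .ct_constants$permeability
  logp_eff <- ct_effective_logp(compound$logp, compound$ionisation)
  p_cell <- .ct_perm_qspr(logp_eff, compound$mw)
  p_int_endo <- k$endothelial_factor *
    (k$p_ref_cm_min * 10^(k$logp_slope * logp_eff) * (compound$mw / k$mw_ref)^(-k$mw_exponent))
  p_endo <- k$p_max_cm_min * p_int_endo / (k$p_max_cm_min + p_int_endo) +
    k$paracellular_floor_cm_min * (k$mw_ref / compound$mw)
  if (is.null(sa_cell_cm2)) {
    stopifnot(inherits(chip, "chip_spec"))
    if (!is.finite(chip$cell_number) || chip$cell_number <= 0)
      stop(sprintf("chip '%s' has no cell number; supply an override", chip$name), call. = FALSE)
    sa_cell_cm2 <- chip$cell_number * .ct_constants$cell_geometry[["membrane_area_cm2"]]
  }
  pa <- p_cell * sa_cell_cm2
  list(P_endothelial = p_endo, PA_int_cell = pa, PA_cell_int = pa,
       sa_cell_cm2 = sa_cell_cm2)
}

#' QSAR unbound intracellular fraction
#'
#' Predicts the unbound fraction of compound in hepatocytes from
#' lipophilicity with the logit-logP binding model
#' `fu_cell = 1 / (1 + 10^(slope * logP_eff + intercept))` (slope 0.4,
#' intercept -1.38; effective logP after the ionisation-class shift).
#' Hydrophilic compounds approach `fu_cell = 1`; binding increases
#' monotonically with lipophilicity. The interface reserves a second model
#' slot (`"fraction_neutral"`) which is not implemented.
#'
#' @param compound a [compound_record()].
#' @param model QSAR model identifier; only `"logit_logp"` is implemented.
#' @return `fu_cell`, a fraction in (0, 1].
#' @export
qsar_fu_cell <- function(compound, model = "logit_logp") {
  stopifnot(inherits(compound, "compound_record"))
  model <- match.arg(model, c("logit_logp", "fraction_neutral"))
  if (model != "logit_logp")
    stop(sprintf("fu_cell model '%s' is not implemented; available: logit_logp", model),
         call. = FALSE)
  q <- .ct_constants$fu_cell_qsar
  logp_eff <- ct_effective_logp(compound$logp, compound$ionisation)
  1 / (1 + 10^(q[["slope"]] * logp_eff + q[["intercept"]]))
}

#' Full partition/permeability parameter set for a compound on a chip
#'
#' Convenience wrapper bundling [compute_partition_coefficients()],
#' [compute_permeabilities()] and [qsar_fu_cell()] into the six downstream
#' parameters plus the intracellular unbound fraction.
#'
#' @inheritParams compute_permeabilities
#' @param method partition method passed to
#'   [compute_partition_coefficients()].
#' @return Named list (class `partition_permeability_set`).
#' @export
compound_parameter_set <- function(compound, chip, method = "poulin_theil",
                                   sa_cell_cm2 = NULL) {
  pp <- c(compute_partition_coefficients(compound, method),
          compute_permeabilities(compound, chip, sa_cell_cm2),
          list(fu_cell = qsar_fu_cell(compound)))
  structure(pp, class = "partition_permeability_set")
}
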