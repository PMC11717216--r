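#' Model constants
#'
#' Single versioned table of the physicochemical, geometric and physiological
#' constants used throughout the package. All downstream parameter
#' calculations (partitioning, permeability, intracellular binding, human
#' scale-up) draw from this list so that every constant is documented and
#' overridable in one place.
#'
#' @details
#' * `tissue_composition`: fractional volumes of water, neutral lipid and
#'   phospholipid used by the Poulin-Theil tissue:water partition equation.
#'   The interstitium is treated as plasma-like, the intracellular space as
#'   hepatocyte (liver)-like.
#' * `ionisation_logp_offset`: fixed shift applied to logP per ionisation
#'   class (-1 acid, 0 neutral, +1 base) to obtain the effective
#'   (distribution-like) logP used in partitioning and permeability. Ionised
#'   species partition into membranes less than the neutral form; the penalty
#'   is larger for anions than for cations (phospholipid affinity partially
#'   compensates for bases).
#' * `permeability`: constants of the transcellular permeability QSPR
#'   (log-linear in effective logP, inverse cubic in molecular weight,
#'   capped by an unstirred-layer maximum) plus the endothelial leakiness
#'   factor and a size-dependent paracellular floor.
#' * `fu_cell_qsar`: slope/intercept of the logit-logP model for the unbound
#'   intracellular fraction in hepatocytes,
#'   `fu_cell = 1 / (1 + 10^(slope * logP_eff + intercept))`.
#' * `cell_geometry`: per-hepatocyte volume (mL), membrane surface area and
#'   projected footprint (cm^2), from a 3400 um^3 spherical cell.
#' * `interstitial_volume_fraction`: interstitial volume as a fraction of the
#'   intracellular volume.
#' * `human`: hepatocellularity (cells per g liver), liver weight (g per kg
#'   body weight) and hepatic blood flow (mL/min/kg) used by the IVIVE step.
#' * `kpuu_grid`, `kpuu_ionisation_factor`: candidate unbound
#'   intracellular-to-media partitioning values scanned when no observed
#'   Kp_uu is available, and the per-ionisation-class multiplier applied to
#'   the grid (bases accumulate intracellularly, acids are excluded).
#'
#' @return Named list of constants.
#' @export
ct_constants <- function() .ct_constants

.ct_constants <- list(
  version = "1",
  tissue_composition = list(
    interstitium = c(water = 0.945, neutral_lipid = 0.0023, phospholipid = 0.0013),
    cell         = c(water = 0.751, neutral_lipid = 0.0348, phospholipid = 0.0252)
  ),
  ionisation_logp_offset = c(`-1` = -1.5, `0` = 0, `1` = -0.5),
  permeability = list(
    p_ref_cm_min = 1e-3,   # intrinsic transcellular permeability at logP_eff 0, MW 300
    logp_slope = 0.5,
    mw_ref = 300,
    mw_exponent = 3,
    p_max_cm_min = 0.06,   # unstirred-layer cap (1e-3 cm/s)
    endothelial_factor = 1,        # transcellular crossing of the monolayer, same cap
    paracellular_floor_cm_min = 1e-4
  ),
  fu_cell_qsar = c(slope = 0.4, intercept = -1.38),
  cell_geometry = c(
    volume_ml = 3.4e-9,        # 3400 um^3 hepatocyte
    membrane_area_cm2 = 1.1e-5,
    footprint_cm2 = 2.7e-6
  ),
  interstitial_volume_fraction = 0.2,
  human = c(
    hepatocellularity_per_g = 120e6,
    liver_weight_g_per_kg = 25.7,
    hepatic_flow_ml_min_kg = 20.7
  ),
  kpuu_grid = c(0.1, 0.3, 1, 3, 10),
  kpuu_ionisation_factor = c(`-1` = 0.5, `0` = 1, `1` = 3)
)

# effective logP after the fixed ionisation-class shift
ct_effective_logp <- function(logp, ionisation) {
  offs <- .ct_constants$ionisation_logp_offset
  logp + unname(offs[as.character(ionisation)])
}
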