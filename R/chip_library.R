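#' Chip hardware specification
#'
#' A `chip_spec` describes the hardware of a liver-on-chip or spheroid plate
#' as a set of well-mixed compartments: the media chamber(s), a thin
#' interstitial layer and the intracellular space of the seeded hepatocytes.
#' Volumes not fixed by the hardware are derived from cell number:
#' `v_intracellular = cell_number * per-cell volume` and
#' `v_interstitium = 0.2 * v_intracellular`; the nominal media/cell-layer
#' exchange area defaults to `cell_number * per-cell footprint`. All derived
#' values can be overridden.
#'
#' @param name identifier for the chip.
#' @param media_volume_ml total media volume (mL).
#' @param cell_number number of seeded hepatocytes.
#' @param n_media_chambers 1 or 2 media chambers.
#' @param recirculating logical; is media recirculated by flow?
#' @param q_mix_ml_min mixing/recirculation flow rate (mL/min); must be > 0
#'   exactly when `recirculating` is `TRUE`.
#' @param sa_med_int_liver_cm2 media/interstitium exchange surface area
#'   (cm^2). `NA` marks it as to-be-estimated; a nominal value is derived
#'   from cell number when `NULL`.
#' @param v_interstitium_ml,v_intracellular_ml compartment volumes (mL);
#'   derived from `cell_number` when `NULL`.
#'
#' @return An object of class `chip_spec`.
#' @export
chip_spec <- function(name, media_volume_ml, cell_number,
                      n_media_chambers = 1, recirculating = FALSE,
                      q_mix_ml_min = 0,
                      sa_med_int_liver_cm2 = NULL,
                      v_interstitium_ml = NULL, v_intracellular_ml = NULL) {
  geom <- .ct_constants$cell_geometry
  if (is.null(v_intracellular_ml) && is.finite(cell_number))
    v_intracellular_ml <- cell_number * geom[["volume_ml"]]
  if (is.null(v_interstitium_ml) && !is.null(v_intracellular_ml))
    v_interstitium_ml <- .ct_constants$interstitial_volume_fraction * v_intracellular_ml
  if (is.null(sa_med_int_liver_cm2) && is.finite(cell_number))
    sa_med_int_liver_cm2 <- cell_number * geom[["footprint_cm2"]]
  spec <- structure(list(
    name = as.character(name),
    media_volume_ml = as.numeric(media_volume_ml),
    cell_number = as.numeric(cell_number),
    n_media_chambers = as.integer(n_media_chambers),
    recirculating = isTRUE(recirculating),
    q_mix_ml_min = as.numeric(q_mix_ml_min),
    sa_med_int_liver_cm2 = as.numeric(if (is.null(sa_med_int_liver_cm2)) NA else sa_med_int_liver_cm2),
    v_interstitium_ml = as.numeric(if (is.null(v_interstitium_ml)) NA else v_interstitium_ml),
    v_intracellular_ml = as.numeric(if (is.null(v_intracellular_ml)) NA else v_intracellular_ml)
  ), class = "chip_spec")
  validate_chip_spec(spec, require_complete = FALSE)
  spec
}

#' Validate a chip specification
#'
#' @param spec a [chip_spec()].
#' @param require_complete if `TRUE`, every geometric field must be a finite
#'   positive number (as required to build the kinetic model); if `FALSE`,
#'   `NA` placeholders (e.g. the `dynamic42` preset awaiting user overrides)
#'   are allowed.
#' @return `spec`, invisibly; errors on violation.
#' @export
validate_chip_spec <- function(spec, require_complete = TRUE) {
  stopifnot(inherits(spec, "chip_spec"))
  chk <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  num_fields <- c("media_volume_ml", "cell_number", "v_interstitium_ml",
                  "v_intracellular_ml")
  if (require_complete) {
    for (f in c(num_fields, "sa_med_int_liver_cm2"))
      chk(is.finite(spec[[f]]) && spec[[f]] > 0,
          sprintf("chip '%s': field '%s' must be a positive number; preset values are placeholders, supply an override (see ?load_chip_preset)", spec$name, f))
  } else {
    for (f in num_fields)
      chk(is.na(spec[[f]]) || spec[[f]] > 0,
          sprintf("chip '%s': field '%s' must be positive when given", spec$name, f))
  }
  chk(spec$n_media_chambers %in% c(1L, 2L), "n_media_chambers must be 1 or 2")
  chk(is.finite(spec$q_mix_ml_min) && spec$q_mix_ml_min >= 0, "q_mix_ml_min must be >= 0")
  chk(identical(spec$recirculating, spec$q_mix_ml_min > 0),
      sprintf("chip '%s': q_mix_ml_min must be > 0 exactly when recirculating", spec$name))
  invisible(spec)
}

#' Names of the shipped chip presets
#' @return Character vector of preset identifiers.
#' @export
chip_preset_names <- function() {
  files <- list.files(system.file("extdata", "chips", package = "chiptwin"),
                      pattern = "\\.yaml$")
  sort(sub("\\.yaml$", "", files))
}

#' Load a chip hardware preset
#'
#' Shipped presets cover the hepatic in vitro systems most commonly used for
#' depletion studies: single-chamber recirculating liver chips (`cnbio`),
#' two-chamber recirculating chips (`javelin`), static 3D spheroid plates at
#' two scales (`hurel1`, `hurel2`), a perfused chip placeholder requiring
#' user-supplied geometry (`dynamic42`), and a generic static single chamber
#' (`generic_one_chamber`).
#'
#' @param name preset identifier; see [chip_preset_names()].
#' @param ... overrides for any [chip_spec()] field (e.g.
#'   `media_volume_ml = 2`).
#' @return A [chip_spec()].
#' @examples
#' load_chip_preset("cnbio")
#' @export
load_chip_preset <- function(name, ...) {
  valid <- chip_preset_names()
  if (!is.character(name) || length(name) != 1L || !(name %in% valid))
    stop(sprintf("preset not found: '%s'. Valid presets: %s",
                 as.character(name)[1], paste(valid, collapse = ", ")), call. = FALSE)
  path <- system.file("extdata", "chips", paste0(name, ".yaml"), package = "chiptwin")
  spec <- read_chip_config(path)
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(spec))
    if (length(bad)) stop("unknown chip_spec field(s): ", paste(bad, collapse = ", "), call. = FALSE)
    fields <- utils::modifyList(unclass(spec)[-1], overrides[setdiff(names(overrides), "name")])
    # geometry left NA by a placeholder preset is re-derived from the
    # (possibly overridden) cell number unless explicitly supplied
    for (f in c("v_intracellular_ml", "v_interstitium_ml", "sa_med_int_liver_cm2"))
      if (!f %in% names(overrides) && is.na(fields[[f]])) fields[[f]] <- NULL
    spec <- do.call(chip_spec, c(list(name = spec$name), fields))
  }
  spec
}

#' Read / write chip configuration files
#'
#' Chip specifications are serialised as YAML with explicit unit suffixes in
#' the field names. `NULL`/missing geometric fields are derived from cell
#' number on read (see [chip_spec()]); `NA` survives a round trip.
#'
#' @param path YAML file path.
#' @return `read_chip_config` returns a [chip_spec()];
#'   `write_chip_config` returns `path` invisibly.
#' @export
read_chip_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("name", "media_volume_ml", "cell_number", "n_media_chambers",
             "recirculating", "q_mix_ml_min", "sa_med_int_liver_cm2",
             "v_interstitium_ml", "v_intracellular_ml")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown field(s) in chip config: ", paste(bad, collapse = ", "), call. = FALSE)
  raw <- lapply(raw, function(x) if (is.character(x) && x %in% c("NA", ".na")) NA_real_ else x)
  do.call(chip_spec, raw)
}

#' @rdname read_chip_config
#' @param spec a [chip_spec()].
#' @export
write_chip_config <- function(spec, path) {
  stopifnot(inherits(spec, "chip_spec"))
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @export
print.chip_spec <- function(x, ...) {
  cat(sprintf("<chip_spec> %s\n", x$name))
  cat(sprintf("  media: %.3g mL in %d chamber(s), %s\n", x$media_volume_ml,
              x$n_media_chambers,
              if (x$recirculating) sprintf("recirculating at %.3g mL/min", x$q_mix_ml_min) else "static"))
  cat(sprintf("  cells: %.3g  (V_i = %.3g mL, V_c = %.3g mL)\n",
              x$cell_number, x$v_interstitium_ml, x$v_intracellular_ml))
  cat(sprintf("  media/interstitium exchange area: %.3g cm2\n", x$sa_med_int_liver_cm2))
  invisible(x)
}
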