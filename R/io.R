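#' Write a trajectory as tidy CSV
#'
#' Long format with one row per time point and compartment:
#' `time_min, compartment, conc_umol_per_ml`.
#'
#' @param traj a `ct_trajectory`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "ct_trajectory"))
  tidy <- data.frame(
    time_min = rep(traj$time_min, 3),
    compartment = rep(c("media", "interstitium", "intracellular"),
                      each = nrow(traj)),
    conc_umol_per_ml = c(traj$C_m, traj$C_i, traj$C_c))
  utils::write.csv(tidy, path, row.names = FALSE)
  invisible(path)
}
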