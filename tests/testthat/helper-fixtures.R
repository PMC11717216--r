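# shared fixtures: built in code, no stored data

ct_test_chip <- function() load_chip_preset("cnbio")

ct_test_compound <- function(logp = 2.5, fu = 0.5, ion = 0) {
  compound_record("testdrug", logp = logp, mw = 350, fu_media = fu, ionisation = ion)
}

# random positive parameter set; volumes span chip-like magnitudes
ct_random_params <- function(cl_c = stats::runif(1, 0, 0.1)) {
  twin_parameters(k1 = stats::runif(1, 1e-4, 0.05),
                  k2 = stats::runif(1, 1e-4, 0.05),
                  k3 = stats::runif(1, 1e-3, 0.5),
                  k4 = stats::runif(1, 1e-3, 2),
                  cl_c = cl_c,
                  v_m = stats::runif(1, 0.05, 2),
                  v_i = stats::runif(1, 1e-4, 0.05),
                  v_c = stats::runif(1, 1e-4, 0.05))
}

# worst-case relative deviation between two trajectories, per compartment
# scaled by that compartment's maximum magnitude
ct_traj_rel_diff <- function(a, b) {
  max(vapply(c("C_m", "C_i", "C_c"), function(col) {
    scale <- max(abs(a[[col]]), 1e-300)
    max(abs(a[[col]] - b[[col]])) / scale
  }, 0))
}
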