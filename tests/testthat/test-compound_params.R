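test_that("a neutral logP 0 compound partitions near unity (no lipid enrichment)", {
  cmp <- compound_record("probe", logp = 0, mw = 300, fu_media = 1)
  pc <- compute_partition_coefficients(cmp)
  # oracle: K = Vw + P*(Vnl + 0.3 Vph) + 0.7 Vph with P = 1
  comp <- ct_constants()$tissue_composition
  k_int <- comp$interstitium[["water"]] +
    (comp$interstitium[["neutral_lipid"]] + 0.3 * comp$interstitium[["phospholipid"]]) +
    0.7 * comp$interstitium[["phospholipid"]]
  k_cell <- comp$cell[["water"]] +
    (comp$cell[["neutral_lipid"]] + 0.3 * comp$cell[["phospholipid"]]) +
    0.7 * comp$cell[["phospholipid"]]
  expect_equal(pc$K_water_int, k_int)
  expect_equal(pc$K_water_cell, k_cell)
  expect_true(all(unlist(pc) > 0.5 & unlist(pc) < 2))
})

test_that("partition coefficients and cell binding are monotone in logP", {
  logps <- seq(-2, 6, by = 0.5)
  for (ion in c(-1L, 0L, 1L)) {
    pcs <- lapply(logps, function(lp)
      compute_partition_coefficients(compound_record("x", lp, 300, 0.5, ion)))
    for (nm in c("K_int_med", "K_water_int", "K_water_cell")) {
      vals <- vapply(pcs, `[[`, 0, nm)
      expect_true(all(vals > 0))
      expect_true(all(diff(vals) >= 0), label = sprintf("%s ion %d", nm, ion))
    }
    fus <- vapply(logps, function(lp)
      qsar_fu_cell(compound_record("x", lp, 300, 0.5, ion)), 0)
    expect_true(all(fus > 0 & fus <= 1))
    expect_true(all(diff(fus) <= 0))
  }
  # explicit pairwise check: more lipophilic binds/partitions more
  k1 <- compute_partition_coefficients(compound_record("a", 1, 300, 0.5))$K_water_cell
  k3 <- compute_partition_coefficients(compound_record("b", 3, 300, 0.5))$K_water_cell
  expect_gt(k3, k1)
})

test_that("unimplemented partition and fu_cell methods raise informative errors", {
  cmp <- ct_test_compound()
  expect_error(compute_partition_coefficients(cmp, method = "schmitt"),
               "not implemented.*poulin_theil")
  expect_error(compute_partition_coefficients(cmp, method = "berezhkovskiy"),
               "not implemented")
  expect_error(qsar_fu_cell(cmp, model = "fraction_neutral"), "not implemented")
})

test_that("fu_cell matches hand evaluation of the logit-logP equation", {
  # 1 / (1 + 10^(0.4*2 - 1.38)) computed independently
  expect_equal(qsar_fu_cell(compound_record("x", 2, 300, 0.5, 0)),
               1 / (1 + 10^(-0.58)), tolerance = 1e-12)
  expect_equal(qsar_fu_cell(compound_record("x", 2, 300, 0.5, 0)),
               0.7917488, tolerance = 1e-7)
  # very hydrophilic compounds are essentially unbound in the cell
  expect_gt(qsar_fu_cell(compound_record("x", -2, 300, 0.5, 0)), 0.8)
})

test_that("permeability-area products scale linearly with membrane area", {
  cmp <- ct_test_compound()
  chip <- ct_test_chip()
  base <- compute_permeabilities(cmp, chip)
  doubled <- compute_permeabilities(cmp, chip, sa_cell_cm2 = 2 * base$sa_cell_cm2)
  expect_equal(doubled$PA_int_cell, 2 * base$PA_int_cell)
  expect_equal(doubled$PA_cell_int, 2 * base$PA_cell_int)
  # doubling cell number doubles the default membrane area
  chip2 <- load_chip_preset("cnbio", cell_number = 2 * chip$cell_number)
  expect_equal(compute_permeabilities(cmp, chip2)$PA_int_cell, 2 * base$PA_int_cell)
})

test_that("permeability falls (or stays) with molecular weight and stays finite", {
  chip <- ct_test_chip()
  for (lp in c(-2, 0, 2, 4, 6)) {
    perms <- vapply(seq(100, 800, by = 50), function(mw)
      compute_permeabilities(compound_record("x", lp, mw, 0.5), chip)$P_endothelial, 0)
    expect_true(all(is.finite(perms) & perms > 0), label = sprintf("logP %g", lp))
    expect_true(all(diff(perms) <= 0), label = sprintf("logP %g", lp))
  }
})

test_that("compound parameter computation is deterministic", {
  cmp <- ct_test_compound()
  chip <- ct_test_chip()
  expect_identical(compound_parameter_set(cmp, chip),
                   compound_parameter_set(cmp, chip))
})

test_that("compound records validate their fields and read from CSV", {
  expect_error(compound_record("x", 2, -10, 0.5), "positive")
  expect_error(compound_record("x", 2, 300, 0), "0, 1")
  expect_error(compound_record("x", 2, 300, 0.5, ionisation = 2), "ionisation")
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write.csv(data.frame(name = c("a", "b"), logp = c(1, 3), mw = c(250, 400),
                       fu_media = c(0.9, 0.2), ionisation = c(0, 1),
                       rbp = c(1.1, NA)),
            path, row.names = FALSE)
  tab <- read_compound_table(path)
  expect_named(tab, c("a", "b"))
  expect_equal(tab$a$rbp, 1.1)
  expect_null(tab$b$rbp)
})
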