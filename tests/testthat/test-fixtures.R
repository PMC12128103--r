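test_that("the packaged barrier table matches the printed values and flags", {
  tb <- load_table1()
  wide <- load_table1(long = FALSE)
  expect_equal(nrow(wide), 30)
  expect_equal(nrow(tb), 300)  # 30 reactions x 5 levels x 2 temperatures
  expect_equal(table1_barrier("xylose", "DXP", "DFT", 298)[[1]], 45.54)
  expect_equal(table1_barrier("xylose", "DXP", "CBS", 0)[[1]], 38.19)
  expect_equal(table1_barrier("4-O-methyl-D-glucuronic-acid", "DGLA",
                              "DLPNO/CBS", 298)[[1]], 46.75)
  # relaxed-convergence flags follow the table footnote
  for (lv in c("DFT", "DLPNO", "DLPNO/CBS"))
    expect_true(attr(table1_barrier("2-O-acetyl-xylose", "FFL2", lv, 298),
                     "relaxed"))
  expect_false(attr(table1_barrier("2-O-acetyl-xylose", "FFL2", "CBS", 298),
                    "relaxed"))
  expect_true(attr(table1_barrier("xylose", "FF1", "CBS", 0), "relaxed"))
  # the unlocatable transition state is missing at every level, never zero
  ffl1 <- tb[tb$reactant == "2-O-acetyl-xylose" & tb$product == "FFL1", ]
  expect_equal(nrow(ffl1), 10)
  expect_true(all(is.na(ffl1$dH)))
  expect_error(table1_barrier("xylose", "XYZ"), "no such record")
})

test_that("the packaged table is locked against edits (frozen digest)", {
  tb <- load_table1()
  expect_equal(sum(!is.na(tb$dH)), 290)
  expect_equal(sum(tb$dH, na.rm = TRUE), 20221.16, tolerance = 1e-9)
  expect_equal(sum(tb$relaxed), 12)  # flagged cells per the table footnote
})

test_that("species composition arithmetic reproduces the printed electron counts", {
  xyl <- build_species("xylose")
  expect_equal(xyl$electron_count, 80)
  expect_equal(unname(xyl$composition[c("C", "H", "O")]), c(5, 10, 5))
  acet <- build_species("xylose", c("2" = "acetyl"))
  expect_equal(acet$electron_count, 102)
  dimer <- build_species("xylose", dimer_partner = build_species("xylose"))
  expect_equal(dimer$electron_count, 150)  # xylobiose
  expect_equal(dimer$topology, "dimer")
  gx <- build_species("xylose", c("4" = "methoxy", "5" = "carboxyl"),
                      dimer_partner = build_species("xylose"))
  expect_equal(gx$electron_count, 180)  # glucuronoxylan
  # condensation conserves electrons: monomer + monomer - H2O
  expect_equal(dimer$electron_count, 2 * xyl$electron_count - 10)
  # group arithmetic commutes
  ab <- build_species("xylose", c("2" = "acetyl", "4" = "methoxy"))
  ba <- build_species("xylose", c("4" = "methoxy", "2" = "acetyl"))
  expect_equal(ab$composition, ba$composition)
  expect_error(build_species("xylose", c("1" = "acetyl")), "positions 2/3")
  expect_error(build_species("xylose", c("4" = "carboxyl")), "position 5")
})

test_that("toy models are normalized in every charge state", {
  suite <- toy_density_suite()
  expect_gte(length(suite), 4)
  for (nm in names(suite)) {
    ent <- suite[[nm]]
    g <- default_grid(ent$neutral$mol)
    for (st in c("neutral", "cation", "anion")) {
      v <- ent[[st]]
      f <- evaluate_model_fields(v$mol, v$orbitals, g)
      expect_equal(integrate_field(f$density), v$mol$n_electrons,
                   tolerance = 1e-3,
                   label = paste(nm, st, "density integral"))
    }
    expect_equal(ent$anion$mol$n_electrons, ent$neutral$mol$n_electrons + 1L)
    expect_equal(ent$cation$mol$n_electrons, ent$neutral$mol$n_electrons - 1L)
  }
})

test_that("synthetic regression data are deterministic and centered on the truth", {
  truth <- coef(epl_model("G4"))
  a <- synthetic_regression_dataset(truth, n = 100, sigma = 0.5, seed = 11)
  b <- synthetic_regression_dataset(truth, n = 100, sigma = 0.5, seed = 11)
  expect_identical(a, b)
  c_ <- synthetic_regression_dataset(truth, n = 100, sigma = 0.5, seed = 12)
  expect_false(identical(a, c_))
  # zero-noise rows lie exactly on the generating plane
  z <- synthetic_regression_dataset(truth, n = 20, sigma = 0, seed = 3)
  expect_equal(z$dH,
               truth[["f_bar"]] * z$f_bar + truth[["n_bar"]] * z$n_bar +
                 truth[["g_bar"]] * z$g_bar + truth[["intercept"]])
  # noisy sample mean matches the model mean within a CLT band
  big <- synthetic_regression_dataset(truth, n = 2000, sigma = 1, seed = 5)
  model_mean <- mean(truth[["f_bar"]] * big$f_bar +
                       truth[["n_bar"]] * big$n_bar +
                       truth[["g_bar"]] * big$g_bar + truth[["intercept"]])
  expect_lt(abs(mean(big$dH) - model_mean), 3 / sqrt(2000))
  expect_error(synthetic_regression_dataset(truth, sigma = -1), "sigma")
})
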