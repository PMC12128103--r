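golden_recipes <- list(
  ring_opening = list(sites = c("C1:f0", "O:f-", "O1:f-"),
                      bonds = "V(C1,O)", pairs = c("C1-O", "O1-H_O1")),
  ring_contraction_FF1 = list(
    sites = c("C1:f0", "C2:f0", "C3:f0", "O1:f-", "O2:f-"),
    bonds = "V(C1,O1)", pairs = c("C2-C3", "C1-O1", "O2-H_O2")),
  ring_contraction_FF2 = list(
    sites = c("C1:f0", "C2:f0", "O:f-", "O1:f-", "O2:f-"),
    bonds = c("V(C1,O)", "V(C2,O2)"),
    pairs = c("C1-O", "C2-O2", "O1-H_O1")),
  elimination1 = list(sites = c("C1:f0", "C2:f0", "O1:f-"),
                      bonds = "V(C1,O1)", pairs = c("C1-O1", "C2-H2")),
  elimination2 = list(sites = c("C2:f0", "C1:f0", "O2:f-"),
                      bonds = "V(C2,O2)", pairs = c("C2-O2", "C1-H1")),
  elimination3 = list(sites = c("C3:f0", "C2:f0", "O2:f-"),
                      bonds = "V(C2,O2)", pairs = c("C2-O2", "C3-H3")),
  elimination4 = list(sites = c("C3:f0", "C2:f0", "O3:f-"),
                      bonds = "V(C3,O3)", pairs = c("C3-O3", "C2-H2")),
  elimination5 = list(sites = c("C4:f0", "C3:f0", "O3:f-"),
                      bonds = "V(C3,O3)", pairs = c("C3-O3", "C4-H4")),
  elimination6 = list(sites = c("C4:f0", "C3:f0", "O4:f-"),
                      bonds = "V(C4,O4)", pairs = c("C4-O4", "C4-H4")),
  elimination7 = list(sites = c("C5:f0", "C4:f0", "O4:f-"),
                      bonds = "V(C4,O4)", pairs = c("C4-O4", "C5-H5")))

test_that("recipes match the published site lists token-for-token", {
  for (nm in names(golden_recipes)) {
    gold <- golden_recipes[[nm]]
    rec <- if (startsWith(nm, "elimination"))
      build_recipe("elimination",
                   position = as.integer(sub("elimination", "", nm)))
    else build_recipe(nm)
    got_sites <- paste(rec$fukui_sites$label, rec$fukui_sites$kind, sep = ":")
    expect_identical(got_sites, gold$sites, label = paste(nm, "sites"))
    expect_identical(rec$bonds, gold$bonds, label = paste(nm, "bonds"))
    expect_identical(rec$pairs, gold$pairs, label = paste(nm, "pairs"))
  }
  expect_error(build_recipe("elimination", position = 8), "1..7")
  expect_error(build_recipe("elimination"), "1..7")
})

test_that("substituted positions relabel the leaving-group pair with a warning", {
  # ring contraction consumes the O2-H_O2 proton transfer: an acetyl at 2
  # replaces that proton, so the pair becomes the ester linkage O2-Cac2
  expect_warning(
    rec <- build_recipe("ring_contraction_FF1",
                        substitutions = c("2" = "acetyl")),
    "leaving-group linkage")
  expect_true("O2-Cac2" %in% rec$pairs)
  expect_false("O2-H_O2" %in% rec$pairs)
  # elimination 2 already references the C2-O2 linkage; the f- site being
  # the ester oxygen is surfaced, not silently reinterpreted
  expect_warning(
    rec2 <- build_recipe("elimination", position = 2,
                         substitutions = c("2" = "acetyl")),
    "linkage oxygen")
  expect_true("C2-O2" %in% rec2$pairs)
  # untouched positions do not warn
  expect_silent(build_recipe("elimination", position = 7,
                             substitutions = c("2" = "acetyl")))
  expect_warning(build_recipe("elimination", position = 7,
                              substitutions = c("5" = "carboxyl")),
                 "carboxyl")
  expect_error(build_recipe("ring_opening",
                            substitutions = c("1" = "acetyl")),
               "illegal substitution")
})

test_that("descriptor aggregation takes plain means and names missing labels", {
  tab <- descriptor_table()
  tab <- add_fukui_rows(tab, "xylose", c("C1", "C2", "O", "O1", "O2"),
                        data.frame(f_plus = rep(NA_real_, 5),
                                   f_minus = c(0.02, 0.01, 0.06, 0.09, 0.05),
                                   f_zero = c(0.03, 0.06, 0.09, 0.04, 0.05)))
  tab <- add_bond_rows(tab, "xylose", c("V(C1,O)", "V(C2,O2)"), c(1.2, 1.4))
  tab <- add_pair_rows(tab, "xylose", c("C1-O", "C2-O2", "O1-H_O1"),
                       c(0.8, 0.4, 0.6))
  ro <- build_recipe("ring_opening")
  agg <- aggregate_descriptors(ro, tab, "xylose")
  expect_equal(agg$f_bar, mean(c(0.03, 0.06, 0.09)))  # C1:f0, O:f-, O1:f-
  expect_equal(agg$n_bar, 1.2)
  expect_equal(agg$g_bar, mean(c(0.8, 0.6)))
  ff2 <- build_recipe("ring_contraction_FF2")
  agg2 <- aggregate_descriptors(ff2, tab, "xylose")
  expect_equal(agg2$n_bar, 1.3)  # mean of V(C1,O), V(C2,O2)
  expect_error(aggregate_descriptors(ro, tab, "glucose"), "xylose|glucose")
  tab2 <- tab[tab$label != "V(C1,O)" | tab$record != "bond", ]
  expect_error(aggregate_descriptors(ro, descriptor_table(tab2), "xylose"),
               "V\\(C1,O\\)")
})

test_that("descriptor tables round-trip through delimited text and reject duplicates", {
  tab <- add_pair_rows(descriptor_table(), "xylose", c("C1-O"), 0.5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_descriptor_table(tab, path)
  back <- read_descriptor_table(path)
  expect_equal(back$value, tab$value)
  expect_error(add_pair_rows(tab, "xylose", "C1-O", 0.7), "duplicate")
})

test_that("packaged EPL polynomials evaluate their published coefficients", {
  zero <- data.frame(f_bar = 0, n_bar = 0, g_bar = 0)
  expect_equal(predict(epl_model("DFT"), zero), -18.80)
  expect_equal(predict(epl_model("DLPNO"), zero), 7.72)
  expect_equal(predict(epl_model("CBS"), zero), 13.96)
  expect_equal(predict(epl_model("G4"), zero), 8.52)
  agg <- structure(list(f_bar = 0.1, n_bar = 1.3, g_bar = 0.5),
                   class = "aggregate_descriptors")
  expect_equal(predict_barrier(epl_model("DFT"), agg), 42.204)
  # affine in the descriptors: midpoint prediction interpolates exactly
  x <- data.frame(f_bar = 0.08, n_bar = 1.1, g_bar = 0.9)
  m <- epl_model("G4")
  expect_equal(predict(m, x / 2),
               (predict(m, zero) + predict(m, x)) / 2)
})

test_that("fit_epl recovers generating coefficients exactly at zero noise", {
  truth <- coef(epl_model("DFT"))
  d <- synthetic_regression_dataset(truth, n = 40, sigma = 0, seed = 7)
  fit <- fit_epl(d)
  expect_equal(coef(fit), truth, tolerance = 1e-8)
  expect_equal(unname(fit$metrics["mae"]), 0, tolerance = 1e-10)
  expect_equal(unname(fit$metrics["r2_adj"]), 1, tolerance = 1e-12)
  expect_error(fit_epl(d[1:3, ]), "nderdetermined")
  collinear <- d
  collinear$g_bar <- 2 * collinear$f_bar
  expect_error(fit_epl(collinear), "collinear")
})

test_that("fitted coefficients cover the truth within 3 SE in >= 95% of replicates", {
  truth <- coef(epl_model("DLPNO"))
  hits <- vapply(1:100, function(r) {
    d <- synthetic_regression_dataset(truth, n = 200, sigma = 1, seed = r)
    fit <- fit_epl(d)
    se <- summary(fit$fit)$coefficients[, "Std. Error"]
    est <- stats::coef(fit$fit)
    truth_lm <- c(truth[["intercept"]], truth[["f_bar"]], truth[["n_bar"]],
                  truth[["g_bar"]])
    all(abs(est - truth_lm) <= 3 * se)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("regression metrics implement MAE, RMSE and adjusted R-squared", {
  ref <- c(1, 2, 3, 4, 5)
  pred <- ref - c(1, -1, 3, 0, 0)
  m <- evaluate_metrics(pred, ref, p = 1)
  expect_equal(unname(m["mae"]), mean(abs(c(1, -1, 3, 0, 0))))
  expect_equal(unname(m["rmse"]), sqrt(mean(c(1, 1, 9, 0, 0))))
  perfect <- evaluate_metrics(ref, ref, p = 1)
  expect_equal(unname(perfect[c("mae", "rmse")]), c(0, 0))
  expect_equal(unname(perfect["r2_adj"]), 1)
  # R2 = 0.9, n = 10, p = 3  =>  R2_adj = 0.85 (checked through the formula)
  set.seed(1)
  refs <- rnorm(10)
  ss_tot <- sum((refs - mean(refs))^2)
  # craft residuals with SS_res = 0.1 * SS_tot
  res <- rep(sqrt(0.1 * ss_tot / 10), 10)
  m2 <- evaluate_metrics(refs - res, refs, p = 3)
  expect_equal(unname(m2["r2_adj"]), 1 - (1 - 0.9) * 9 / 6)
  expect_error(evaluate_metrics(1:4, 1:4, p = 3), "requires n > p")
  # MAE <= RMSE for arbitrary residual vectors
  for (i in 1:20) {
    r <- rnorm(30)
    mm <- evaluate_metrics(r, numeric(30), p = 1)
    expect_lte(mm[["mae"]], mm[["rmse"]])
  }
})

test_that("dataset splits are deterministic, sized and stratified", {
  s1 <- split_dataset(100, fraction = 0.8, seed = 42)
  s2 <- split_dataset(100, fraction = 0.8, seed = 42)
  expect_identical(s1, s2)
  expect_length(s1$train, 80)
  expect_length(s1$validation, 20)
  expect_setequal(c(s1$train, s1$validation), 1:100)
  cls <- factor(rep(c("a", "b", "c"), times = c(50, 30, 20)))
  st <- split_dataset(100, fraction = 0.8, seed = 1, stratify = cls)
  counts <- table(cls[st$train])
  expect_true(all(abs(counts - c(40, 24, 16)) <= 1))
  expect_error(split_dataset(3, stratify = factor(c("a", "a", "b"))),
               ">= 2 rows")
  expect_error(split_dataset(10, fraction = 1.2), "fraction")
})

test_that("aggregation is permutation-invariant within each descriptor list", {
  tab <- descriptor_table()
  tab <- add_fukui_rows(tab, "s", c("C1", "C2", "O1"),
                        data.frame(f_plus = 1:3, f_minus = c(0.2, 0.3, 0.4),
                                   f_zero = c(0.1, 0.5, 0.3)))
  tab <- add_pair_rows(tab, "s", c("C1-O1", "C2-H2"), c(0.9, 0.1))
  tab <- add_bond_rows(tab, "s", "V(C1,O1)", 1.5)
  rec <- build_recipe("elimination", position = 1)
  base <- aggregate_descriptors(rec, tab, "s")
  shuffled <- descriptor_table(as.data.frame(tab)[sample(nrow(tab)), ])
  again <- aggregate_descriptors(rec, shuffled, "s")
  expect_equal(again$f_bar, base$f_bar)
  expect_equal(again$g_bar, base$g_bar)
})
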