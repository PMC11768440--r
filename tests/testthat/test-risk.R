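test_that("dose formulas reproduce hand-evaluated worked values", {
  f <- exposure_factors()
  expect_equal(add_ingestion(29.89, f), 29.89 * 100 / 70 * 1e-6, tolerance = 1e-12)
  expect_equal(signif(add_ingestion(29.89, f), 4), 4.270e-5)
  expect_equal(add_inhalation(29.89, f), 29.89 * 20 / (1.36e9 * 70), tolerance = 1e-12)
  expect_equal(signif(add_inhalation(29.89, f), 4), 6.279e-9)
  expect_equal(add_dermal(29.89, f), 29.89 * 5700 * 0.07 * 0.001 * 1e-6 / 70, tolerance = 1e-12)
  expect_equal(signif(add_dermal(29.89, f), 4), 1.704e-7)
  # zero dose at zero concentration, all paths
  expect_identical(add_ingestion(0, f), 0)
  expect_identical(add_inhalation(0, f), 0)
  expect_identical(add_dermal(0, f), 0)
  expect_error(add_ingestion(-1, f), "non-negative")
})

test_that("algebraic structure of the dose chain holds", {
  f <- exposure_factors()
  # inhalation/ingestion ratio is concentration-free
  for (c in c(0.5, 29.89, 1000))
    expect_equal(add_inhalation(c, f) / add_ingestion(c, f),
                 f$R_inh / (f$R_ing * f$PEF * 1e-6), tolerance = 1e-12)
  expect_equal(add_inhalation(1, f) / add_ingestion(1, f), 1.4706e-4, tolerance = 1e-4)
  # unit-cancellation: c = BW*1e6/R_ing with EF*ED = AT gives a unit dose
  expect_equal(add_ingestion(70e6 / 100, f), 1.0)
  # dermal collapses onto ingestion when SA*SL = R_ing and ABS = 1
  g <- exposure_factors(SA = 1000, SL = 0.1, ABS = 1)
  expect_equal(add_dermal(5, g), add_ingestion(5, g), tolerance = 1e-15)
  # default averaging time makes EF*ED/AT exactly 1
  expect_identical(f$EF * f$ED / f$AT, 1)
})

test_that("reference-dose fixture carries the published Fe row", {
  rfd <- rfd_table()
  fe <- rfd[rfd$metal == "Fe", ]
  expect_equal(fe$ing, 0.7)
  expect_equal(fe$derm, 2.2e-4)
  expect_equal(fe$inh, 7e-3)
  expect_setequal(rfd$metal, metals10)
  expect_true(all(rfd$ing > 0 & rfd$derm > 0 & rfd$inh > 0))
})

test_that("Fe hazard quotients at the worked concentrations match the published range", {
  conc <- matrix(fe_reference_concentrations(), ncol = 1,
                 dimnames = list(c("Dmin", "Dmax"), "Fe"))
  hz <- hazard_quotients(conc)
  expect_equal(signif(hz$HQ_path["Dmin", "Fe", "ing"], 3), 6.10e-5)
  expect_equal(signif(hz$HQ_path["Dmax", "Fe", "ing"], 3), 2.57e-4)
  expect_equal(signif(hz$HQ_path["Dmin", "Fe", "inh"], 3), 8.97e-7)
  expect_equal(signif(hz$HQ_path["Dmax", "Fe", "inh"], 3), 3.78e-6)
  # inversion of the ingestion chain recovers the worked concentrations
  expect_equal(concentration_from_hq_ing(6.10e-5, 0.7), 29.89, tolerance = 1e-12)
  expect_equal(concentration_from_hq_ing(2.57e-4, 0.7), 125.93, tolerance = 1e-12)
})

test_that("HQ_metal is the path sum and equals 3 when every dose sits at its reference", {
  f <- exposure_factors()
  c0 <- 12.3
  rfd1 <- data.frame(metal = "Xx", ing = add_ingestion(c0, f),
                     derm = add_dermal(c0, f), inh = add_inhalation(c0, f))
  hz <- hazard_quotients(matrix(c0, 1, 1, dimnames = list("D1", "Xx")), f, rfd1)
  expect_equal(unname(hz$HQ_metal[1, 1]), 3, tolerance = 1e-12)
  # general decomposition on a synthetic table
  ds <- generate_dataset(synthetic_config(seed = 3))
  hz2 <- hazard_quotients(ds$concentrations)
  recon <- hz2$HQ_path[, , "ing"] + hz2$HQ_path[, , "inh"] + hz2$HQ_path[, , "derm"]
  expect_equal(hz2$HQ_metal, recon, tolerance = 1e-14)
  expect_equal(hz2$HI, rowSums(hz2$HQ_metal), tolerance = 1e-14)
})

test_that("hazard index is additive, homogeneous of degree 1, and strictly thresholded", {
  f <- exposure_factors()
  conc <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("Fe", "Zn")))
  hz0 <- hazard_quotients(conc, f)
  expect_equal(unname(hz0$HI), c(0, 0))
  expect_false(any(hz0$risk_flag))

  # build a single-metal table whose HI is exactly 1, then scale it
  c0 <- 5
  rfd1 <- data.frame(metal = "Xx", ing = 3 * add_ingestion(c0, f),
                     derm = 3 * add_dermal(c0, f), inh = 3 * add_inhalation(c0, f))
  m1 <- matrix(c0, 1, 1, dimnames = list("D1", "Xx"))
  expect_equal(unname(hazard_quotients(m1, f, rfd1)$HI), 1, tolerance = 1e-12)
  expect_false(hazard_quotients(m1, f, rfd1)$risk_flag[[1]])      # HI = 1 is safe
  expect_true(hazard_quotients(m1 * 1.5, f, rfd1)$risk_flag[[1]]) # HI = 1.5 flags

  # degree-1 homogeneity: doubling the table doubles ADD, HQ, HI exactly
  ds <- generate_dataset(synthetic_config(seed = 11))
  h1 <- hazard_quotients(ds$concentrations)
  h2 <- hazard_quotients(ds$concentrations * 2)
  expect_identical(h2$ADD, h1$ADD * 2)
  expect_identical(h2$HQ_path, h1$HQ_path * 2)
  expect_equal(h2$HI, h1$HI * 2, tolerance = 1e-15)
})

test_that("dose summary reports extremes with sites and resolves ties to first", {
  conc <- matrix(fe_reference_concentrations(), ncol = 1,
                 dimnames = list(c("D1", "D2"), "Fe"))
  s <- summarize_add(hazard_quotients(conc))
  ing <- s[s$metal == "Fe" & s$path == "ing", ]
  expect_equal(signif(ing$min, 4), 4.270e-5)
  expect_equal(ing$min_site, "D1")
  expect_equal(signif(ing$max, 4), 1.799e-4)
  expect_equal(ing$max_site, "D2")
  expect_true(all(s$min <= s$mean + 1e-15 & s$mean <= s$max + 1e-15))
  expect_equal(s$min_x1e8, s$min * 1e8)

  one <- summarize_add(hazard_quotients(matrix(7, 1, 1, dimnames = list("solo", "Fe"))))
  expect_true(all(one$min == one$max & one$max == one$mean))

  tie <- summarize_add(hazard_quotients(matrix(c(3, 3), 2, 1,
                                               dimnames = list(c("first", "second"), "Fe"))))
  expect_true(all(tie$min_site == "first" & tie$max_site == "first"))
})

test_that("missing reference doses raise a keyed error", {
  conc <- matrix(1, 1, 2, dimnames = list("D1", c("Fe", "Unobtainium")))
  expect_error(hazard_quotients(conc), "Unobtainium")
  expect_error(hazard_quotients(conc), "known")
})
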