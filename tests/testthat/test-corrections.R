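# the ten-formula registry: frozen worked examples, reference fixed
# points, monotonicity, and the Chihara structural-term bound

test_that("registry lists ten formulas with their requirements", {
  reg <- correction_formulas()
  expect_setequal(reg$formula_id,
                  c("shimmyo", "shimmyo_r", "elsheikh2009", "elsheikh2011",
                    "srodka", "chihara", "doughty", "foster", "kohlhaas",
                    "ehlers"))
  expect_equal(reg$requires[reg$formula_id == "foster"], "")
  expect_equal(reg$requires[reg$formula_id == "srodka"], "cct,r")
})

test_that("worked single-record examples match hand arithmetic", {
  # (formula, gat, cct, r) -> frozen expected value
  expect_equal(correct("doughty", gat = 15, cct_um = 545), 15)
  expect_equal(correct("kohlhaas", gat = 15, cct_um = 525), 16.0725)
  expect_equal(correct("foster", gat = 15.5), 22.24)
  expect_equal(correct("ehlers", gat = 15, cct_um = 510), 15.71)
  # at reference geometry the multiplier is 1, so the result is the
  # calibration polynomial -1.61 + 0.94 g + 0.011 g^2
  expect_equal(correct("srodka", gat = 15.5, cct_um = 550, r_mm = 7.8),
               15.60275, tolerance = 1e-9)
  # mm-unit reading: structural fraction ~2e-7, result ~ gat + 4.15
  expect_equal(correct("chihara", gat = 15.5, cct_um = 550, r_mm = 7.8),
               19.65, tolerance = 1e-3)
  # identity coefficients leave the reading unchanged
  expect_equal(correct("elsheikh2009", gat = 17, cct_um = 550, r_mm = 7.8,
                       age = 40), 17)
  expect_equal(correct("elsheikh2011", gat = 17, cct_um = 550, r_mm = 7.8,
                       age = 40), 17)
})

test_that("reference-value fixed points leave the reading unchanged", {
  gat <- c(10, 15.5, 22)
  expect_equal(correct("doughty", gat, cct_um = 545), gat)
  expect_equal(correct("ehlers", gat, cct_um = 520), gat)
  expect_equal(correct("shimmyo", gat, cct_um = 550), gat)
  expect_equal(correct("shimmyo_r", gat, cct_um = 550, r_mm = 7.848837), gat)
  # srodka's fixed point: at reference geometry the formula reduces to the
  # calibration polynomial; locate its fixed point g* and assert stability
  g_star <- uniroot(function(g)
    correct("srodka", g, cct_um = 550, r_mm = 7.8) - g, c(5, 60))$root
  expect_equal(correct("srodka", g_star, cct_um = 550, r_mm = 7.8), g_star,
               tolerance = 1e-6)
})

test_that("CCT monotonicity and Foster slope hold", {
  cct <- seq(400, 700, by = 10)
  for (fid in c("kohlhaas", "doughty", "ehlers", "shimmyo")) {
    out <- correct(fid, gat = 16, cct_um = cct)
    expect_true(all(diff(out) < 0), label = paste(fid, "decreasing in CCT"))
  }
  gat <- seq(8, 30, by = 0.5)
  out <- correct("foster", gat)
  expect_equal(diff(out) / diff(gat), rep(1.08, length(gat) - 1))
})

test_that("chihara (mm reading) differs from gat + 4.15 by < 1e-3 over the validity box", {
  grid <- expand.grid(gat = c(1, 15, 40, 79.9),
                      cct = c(350, 550, 750),
                      r = c(5, 7.8, 11))
  out <- correct("chihara", gat = grid$gat, cct_um = grid$cct, r_mm = grid$r)
  expect_lt(max(abs(out - (grid$gat + 4.15))), 1e-3)
  # the um sensitivity variant applies a visible shrinkage instead
  out_um <- correct("chihara", gat = 15.5, cct_um = 550, r_mm = 7.8,
                    params = list(units = "um"))
  expect_lt(out_um, 19.65 - 0.1)
})

test_that("shimmyo variants follow their documented exponent readings", {
  g <- 16; cct <- 520
  expect_equal(correct("shimmyo", g, cct), g + (550 - cct) / 18)
  expect_equal(correct("shimmyo", g, cct, params = list(variant = "power")),
               g + (550 - cct) / 18^(0.005 * g))
  expect_equal(correct("shimmyo", g, cct, params = list(variant = "literal")),
               g + (550 - cct) / 18^(-0.005 * g))
  expect_error(correct("shimmyo", g, cct, params = list(variant = "bogus")),
               class = "tonocorr_usage_error")
})

test_that("elsheikh accepts config-supplied coefficient polynomials", {
  # constant product 1/0.9 scales the reading by 0.9
  cf <- list(a_cct = 1 / 0.9, a_r = 1, a_age = 1, a_iop = 1)
  expect_equal(correct("elsheikh2009", 20, 550, 7.8, 40,
                       params = list(coef = cf)), 18, tolerance = 1e-12)
  # polynomial in cct: a_cct = 0.5 + 0.001 * cct => 1.05 at 550 um
  cf2 <- list(a_cct = c(0.5, 0.001), a_r = 1, a_age = 1, a_iop = 1)
  expect_equal(correct("elsheikh2011", 21, 550, 7.8, 40,
                       params = list(coef = cf2)), 21 / 1.05)
  # non-positive product is a numeric error, not NaN
  cf3 <- list(a_cct = -1, a_r = 1, a_age = 1, a_iop = 1)
  expect_error(correct("elsheikh2009", 20, 550, 7.8, 40,
                       params = list(coef = cf3)),
               class = "tonocorr_numeric_error")
})

test_that("missing required inputs raise dependency errors naming the formula", {
  expect_error(correct("kohlhaas", gat = 15), "kohlhaas",
               class = "tonocorr_dependency_error")
  expect_error(correct("srodka", gat = 15, cct_um = 550), "r_mm",
               class = "tonocorr_dependency_error")
  expect_error(correct("nosuch", gat = 15), class = "tonocorr_usage_error")
})

test_that("non-positive corrected IOP warns but is returned unclamped", {
  # ehlers at very thick cornea and tiny reading goes non-positive
  expect_warning(out <- correct("ehlers", gat = 1, cct_um = 750),
                 "not clamped")
  expect_equal(out, 1 + 0.071 * (520 - 750))
})

test_that("correct_cohort aligns with per-record correct()", {
  co <- make_test_cohort(7)
  for (fid in correction_formulas()$formula_id) {
    series <- correct_cohort(fid, co)
    expect_length(series, 7)
    one <- correct(fid, gat = co$iop_gat[3], cct_um = co$cct_um[3],
                   r_mm = co$r_mm[3], age = co$age[3])
    expect_equal(series[3], one, label = fid)
  }
  # doughty at reference thickness reproduces the GAT column
  co545 <- make_test_cohort(4, cct = rep(545, 4))
  expect_equal(correct_cohort("doughty", co545), co545$iop_gat)
  # foster is elementwise affine
  expect_equal(correct_cohort("foster", co), 1.08 * co$iop_gat + 5.5)
  expect_error(correct_cohort("foster", data.frame(iop_gat = 1)),
               class = "tonocorr_usage_error")
})

test_that("mean of an affine correction equals the correction at the mean CCT", {
  co <- make_test_cohort(31, gat = rep(16, 31),
                         cct = seq(480, 620, length.out = 31))
  for (fid in c("kohlhaas", "doughty", "ehlers", "shimmyo")) {
    expect_equal(mean(correct_cohort(fid, co)),
                 correct(fid, gat = 16, cct_um = mean(co$cct_um)),
                 tolerance = 1e-9, label = fid)
  }
})
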