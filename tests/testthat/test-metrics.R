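ref <- load_reference_metrics()

test_that("cardiac metrics reproduce the reported baseline and S04 rows", {
  m <- cardiac_metrics(142.789, 65.248, 60)
  expect_equal(m$SV, 77.541)
  expect_equal(round_half_away(m$LVEF, 3), 54.305)
  expect_equal(round_half_away(m$CO, 3), 4.652)
  m <- cardiac_metrics(136.392, 54.962, 60)
  expect_equal(m$SV, 81.430)
  expect_equal(round_half_away(m$CO, 3), 4.886)
  # SV -> 0 as ESV -> EDV
  expect_equal(cardiac_metrics(100, 100 - 1e-6)$SV, 1e-6)
  expect_error(cardiac_metrics(100, 100), "EDV > ESV")
  expect_error(cardiac_metrics(100, 50, HR = 0), "heart rate")
})

test_that("percent change matches the reported two-decimal convention", {
  expect_equal(round_half_away(percent_change(67.998, 77.541), 2), -12.31)
  expect_equal(round_half_away(percent_change(85.827, 142.789), 2), -39.89)
  expect_equal(percent_change(5, 5), 0)
  expect_error(percent_change(1, 0), "baseline")
})

test_that("the metric report reproduces every reported derived cell", {
  rep <- metric_report(ref)
  expect_equal(rep$SV_mL, ref$SV_mL)
  expect_equal(rep$LVEF_pct, ref$LVEF_pct)
  expect_equal(rep$CO_Lmin, ref$CO_Lmin)
  chg <- load_reported_changes()
  got <- rep[match(chg$id, rep$id), ]
  for (col in c("EDV_chg", "ESV_chg", "SV_chg", "LVEF_chg", "CO_chg")) {
    expect_equal(got[[col]], chg[[col]], info = col)
  }
  expect_true(all(is.na(rep[rep$id == "S00",
                            c("EDV_chg", "SV_chg", "CO_chg")])))
})

test_that("OLS sensitivity reproduces the reported Lr-series EDV/ESV rows", {
  lr <- c(1.75, 1.80, 1.85, 1.90, 1.95)
  edv <- ref$EDV_mL[match(c("S01", "S02", "S00", "S03", "S04"), ref$id)]
  r <- ols_sensitivity(lr, edv, 1.85, 142.789)
  expect_equal(r$slope, -53.3, tolerance = 1e-6)
  expect_equal(r$S_star, -0.691, tolerance = 0.005)
  expect_equal(r$R2, 0.987, tolerance = 0.001)
  esv <- ref$ESV_mL[match(c("S01", "S02", "S00", "S03", "S04"), ref$id)]
  expect_equal(ols_sensitivity(lr, esv, 1.85, 65.248)$slope, -121.2,
               tolerance = 1e-6)
  # zero-variance response: slope, S*, R2 all 0 by convention
  r0 <- ols_sensitivity(lr, rep(5, 5), 1.85, 5)
  expect_equal(c(r0$slope, r0$S_star, r0$R2), c(0, 0, 0))
  expect_error(ols_sensitivity(c(1, 2), c(1, 2), 1, 1), "3 points")
  expect_error(ols_sensitivity(rep(1, 3), 1:3, 1, 1), "degenerate")
})

test_that("piecewise segments reproduce the reported below-baseline slopes", {
  pw <- piecewise_sensitivity(ref)
  get <- function(seg, met, col)
    pw[pw$segment == seg & pw$metric == met, col]
  expect_equal(get("S11-S12-S00", "EDV", "slope"), 569.6, tolerance = 0.05)
  expect_equal(get("S11-S12-S00", "EDV", "S_star"), 6.303, tolerance = 0.005)
  expect_equal(get("S21-S22-S00", "SV", "slope"), 486.2, tolerance = 0.05)
  expect_equal(get("S21-S22-S00", "SV", "S_star"), 11.600, tolerance = 0.005)
  expect_equal(nrow(pw), 20L)  # 4 segments x 5 metrics
  # a missing scenario is reported by name
  expect_error(piecewise_sensitivity(ref[ref$id != "S13", ]), "S13")
})

test_that("deviation scores follow the two reference-score definitions", {
  expect_equal(aps_deviation(5, 5, 1), 0)
  expect_equal(aps_deviation(7, 5, 1), 1)        # mu + 2 sigma
  expect_equal(aps_deviation(4.5, 5, 1), 0)      # inside the band
  expect_error(aps_deviation(1, 0, 0), "sigma")
  expect_equal(range_deviation(102, 102, 202), 0)
  expect_equal(range_deviation(302, 102, 202), 1)  # U + (U - L)
  expect_error(range_deviation(1, 2, 2), "U > L")
  # affine re-uniting of metric and bounds leaves the score unchanged
  x <- c(80, 150, 230); a <- 7.5; b <- -3
  expect_equal(range_deviation(a * x + b, a * 102 + b, a * 202 + b),
               range_deviation(x, 102, 202))
})

test_that("S11 deviation scores against the normal ranges match hand arithmetic", {
  ds <- deviation_scores(ref)
  s11 <- ds[ds$id == "S11", ]
  expect_equal(unlist(s11[c("EDV", "ESV", "SV", "LVEF", "CO")],
                      use.names = FALSE),
               c((102 - 85.827) / 100, 0, (57 - 35.082) / 93,
                 (50 - 40.875) / 15, (4 - 2.105) / 4))
  expect_equal(s11$total, 1.47949, tolerance = 1e-5)
  expect_equal(ds$total[ds$id == "S00"], 0)
})

test_that("scenario ranking is descending with lexicographic ties", {
  sc <- data.frame(id = c("S00", "S11"), total = c(0, 1.479))
  expect_equal(rank_scenarios(sc)$id, c("S11", "S00"))
  tie <- data.frame(id = c("S03", "S01", "S02"), total = c(0, 0, 0))
  expect_equal(rank_scenarios(tie)$id, c("S01", "S02", "S03"))
})

test_that("strain conversions are consistent and round-trip", {
  expect_equal(nominal_strain(1), 0)
  expect_equal(green_to_nominal(0), 0)
  expect_equal(green_to_nominal(0.04), sqrt(1.08) - 1)
  lam <- seq(0.2, 2, by = 0.1)
  expect_equal(green_to_nominal((lam^2 - 1) / 2), nominal_strain(lam))
  expect_error(nominal_strain(0), "stretch")
  expect_error(green_to_nominal(-0.6), "2E")
})
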