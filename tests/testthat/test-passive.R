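pp <- passive_params()

test_that("sheet-normal stretch preserves volume and rejects bad input", {
  expect_equal(sheet_normal_stretch(1, 1), 1)
  expect_equal(sheet_normal_stretch(1.3, 1.3), 1 / 1.69)
  expect_equal(sheet_normal_stretch(1.1, 1.0), 1 / 1.1)
  lf <- c(1.05, 1.2, 0.9); ls <- c(1.1, 0.95, 1.3)
  expect_equal(lf * ls * sheet_normal_stretch(lf, ls), rep(1, 3))
  expect_error(sheet_normal_stretch(0, 1), "stretch")
  expect_error(sheet_normal_stretch(1, -2), "stretch")
})

test_that("biaxial kinematics assemble the invariants of the incompressible state", {
  st <- kinematics_from_biaxial(1, 1)
  expect_equal(st$I1_bar, 3)
  expect_equal(st$I4f, 1)
  expect_equal(st$I4s, 1)
  expect_equal(st$J, 1)
  st <- kinematics_from_biaxial(1.1, 1.0)
  expect_equal(st$I1_bar, 1.21 + 1 + 1 / 1.21)
  st <- kinematics_from_biaxial(1.2, 1.1)
  expect_equal(st$I4f, 1.44)
  expect_equal(st$I4s, 1.21)
  expect_equal(st$I8fs, 0)
})

test_that("strain energy vanishes at identity and matches scalar evaluation", {
  at_id <- strain_energy(pp, kinematics_from_biaxial(1, 1))
  expect_equal(at_id$psi_total, 0)
  expect_equal(at_id$psi_vol, 0)   # J = 1
  # independent scalar evaluation of the isotropic term at (1.1, 1.0)
  i1 <- 1.1^2 + 1 + 1 / 1.1^2
  psi_iso_expected <- 0.004 / 16 * (exp(8 * (i1 - 3)) - 1)
  expect_equal(psi_iso_expected, 8.46317e-5, tolerance = 1e-5)
  en <- strain_energy(pp, kinematics_from_biaxial(1.1, 1.0))
  expect_equal(en$psi_iso, psi_iso_expected)
  # non-negativity over a stretch grid, including contracted states
  for (lf in c(0.8, 0.9, 1.0, 1.1, 1.3)) {
    for (ls in c(0.85, 1.0, 1.2)) {
      en <- strain_energy(pp, kinematics_from_biaxial(lf, ls))
      expect_true(all(unlist(en) >= 0))
      expect_equal(en$psi_total,
                   en$psi_iso + en$psi_fiber + en$psi_sheet +
                     en$psi_coupling + en$psi_vol)
    }
  }
})

test_that("closed-form biaxial stresses match independent arithmetic", {
  s <- cauchy_biaxial(pp, 1, 1)
  expect_equal(s$sigma_ff, 0)
  expect_equal(s$sigma_ss, 0)
  # independent evaluation of the closed forms at (1.1, 1.0)
  lf2 <- 1.21; ln2 <- 1 / 1.21
  iso <- 0.004 * exp(8 * (lf2 + 1 + ln2 - 3))
  ff <- iso * (lf2 - ln2) + 2 * 0.005 * (lf2 - 1) * exp(5 * (lf2 - 1)^2) * lf2
  ss <- iso * (1 - ln2)
  expect_equal(ff, 5.222e-3, tolerance = 2e-4)
  expect_equal(ss, 9.29e-4, tolerance = 5e-4)
  s <- cauchy_biaxial(pp, 1.1, 1.0)
  expect_equal(s$sigma_ff, ff)
  expect_equal(s$sigma_ss, ss)
  # equibiaxial symmetry when fiber and sheet moduli coincide
  pp_sym <- passive_params(a_f = 0.005, b_f = 5, a_s = 0.005, b_s = 5)
  s <- cauchy_biaxial(pp_sym, 1.25, 1.25)
  expect_equal(s$sigma_ff, s$sigma_ss)
})

test_that("analytic stresses agree with the finite-difference oracle on a grid", {
  grid <- seq(1.0, 1.3, by = 0.05)
  for (lf in grid) {
    for (ls in grid) {
      ana <- cauchy_biaxial(pp, lf, ls)
      num <- numeric_stress_oracle(pp, lf, ls)
      expect_lt(abs(ana$sigma_ff - num$sigma_ff), 1e-6)
      expect_lt(abs(ana$sigma_ss - num$sigma_ss), 1e-6)
    }
  }
  z <- numeric_stress_oracle(pp, 1, 1)
  expect_lt(abs(z$sigma_ff), 1e-8)
  expect_lt(abs(z$sigma_ss), 1e-8)
  expect_error(numeric_stress_oracle(pp, 1.1, 1.1, h = 0), "h must be")
})

test_that("sigma_ff is strictly increasing in lambda_f at fixed lambda_s", {
  for (ls in c(1.0, 1.15, 1.3)) {
    lf <- seq(1.0, 1.3, by = 0.02)
    s <- cauchy_biaxial(pp, lf, ls)$sigma_ff
    expect_true(all(diff(s) > 0))
  }
})

test_that("anisotropic terms isolate: a_f = 0 leaves only the isotropic part", {
  pp0 <- passive_params(a_f = 0, a_s = 0)
  st <- kinematics_from_biaxial(1.2, 1.0)
  iso_only <- pp0$a * exp(pp0$b * (st$I1_bar - 3)) *
    (st$lambda_f^2 - st$lambda_n^2)
  expect_equal(cauchy_biaxial(pp0, 1.2, 1.0)$sigma_ff, iso_only)
  # reinforcement is tension-only: no anisotropic stress in contraction
  pp_full <- passive_params()
  s_comp <- cauchy_biaxial(pp_full, 0.9, 1.0)
  s_comp0 <- cauchy_biaxial(pp0, 0.9, 1.0)
  expect_equal(s_comp$sigma_ff, s_comp0$sigma_ff)
})

test_that("parameter validation rejects non-physical sets", {
  expect_error(passive_params(a = -1), "moduli")
  expect_error(passive_params(b = 0), "exponents")
  expect_error(passive_params(D = 0), "D must be")
})
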