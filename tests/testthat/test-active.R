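ap <- active_params()

test_that("sarcomere length follows the Green-Lagrange strain", {
  expect_equal(sarcomere_length(0, 1.85), 1.85)
  expect_equal(sarcomere_length(0.105, 1.85), 1.85 * sqrt(1.21))
  expect_equal(sarcomere_length(-0.095, 1.85), 1.85 * sqrt(0.81))
  expect_error(sarcomere_length(-0.5, 1.85), "compression")
})

test_that("ECa50 matches direct arithmetic and diverges at the threshold", {
  # baseline: B*(L - L0) = 4750 * 0.27e-3 = 1.2825
  expect_equal(eca50(0, ap), 4.35 / sqrt(exp(1.2825) - 1))
  expect_equal(eca50(0, ap), 2.694833, tolerance = 1e-6)
  ap17 <- active_params(L_r = 1.75, L_0 = 1.58)   # SLD 0.17
  expect_equal(eca50(0, ap17), 4.35 / sqrt(exp(0.8075) - 1))
  expect_equal(eca50(0, ap17), 3.902805, tolerance = 1e-6)
  # L -> L0+ : activation becomes impossible
  E_at_threshold <- ((1.58 / 1.85)^2 - 1) / 2
  expect_equal(eca50(E_at_threshold, ap), Inf)
  expect_gt(eca50(E_at_threshold + 1e-9, ap), 1e3)
})

test_that("relaxation duration is affine in length under the mm-s convention", {
  expect_equal(relaxation_duration(1.85, ap), 1048.9 * 1.85e-3 - 1.429)
  expect_equal(relaxation_duration(1.85, ap), 0.511465)
  expect_equal(relaxation_duration(1.75, ap), 0.406575)
  expect_equal(relaxation_duration(1.95, ap), 0.616355)
  expect_error(relaxation_duration(-1, ap), "length")
  expect_error(relaxation_duration(1.0, ap), "positive")  # t_r < 0 at 1.0 um
})

test_that("activation phase is piecewise continuous and closes the waveform", {
  expect_equal(activation_phase(0, 0, ap), 0)
  expect_equal(activation_phase(ap$t0, 0, ap), pi)
  expect_equal(activation_phase(ap$t0 - 1e-9, 0, ap), pi, tolerance = 1e-6)
  doc <- duration_of_contraction(ap)
  expect_equal(activation_phase(doc, 0, ap), 0)
  # left limit of the phase is 2*pi, so (1 - cos) -> 0 continuously
  expect_equal(activation_phase(doc - 1e-9, 0, ap), 2 * pi, tolerance = 1e-6)
  expect_error(activation_phase(-0.1, 0, ap), "time")
})

test_that("active stress follows the closed form and stays in [0, T_max]", {
  expect_equal(active_fiber_stress(0, 0, ap), 0)
  peak_expected <- 0.1 * 18.9225 / (18.9225 + (4.35 / sqrt(exp(1.2825) - 1))^2)
  expect_equal(peak_expected, 0.07227, tolerance = 1e-4)
  expect_equal(active_fiber_stress(ap$t0, 0, ap), peak_expected)
  expect_equal(active_fiber_stress(duration_of_contraction(ap) + 0.01, 0, ap), 0)
  # bounded for a sweep of times and strains
  tt <- seq(0, 1, by = 0.01)
  for (E in c(-0.1, 0, 0.1, 0.2)) {
    s <- active_fiber_stress(tt, E, ap)
    expect_true(all(s >= 0 & s <= ap$T_max))
  }
  # below threshold the stress is zero, not an error
  E_below <- ((1.50 / 1.85)^2 - 1) / 2
  expect_equal(active_fiber_stress(ap$t0, E_below, ap), 0)
})

test_that("peak isometric stress is a function of the length difference only", {
  expect_equal(peak_isometric_stress(ap), 0.0722657, tolerance = 1e-6)
  ap_s2_lo <- active_params(L_r = 1.75, L_0 = 1.48)
  ap_s2_hi <- active_params(L_r = 1.95, L_0 = 1.68)
  expect_identical(peak_isometric_stress(ap_s2_lo),
                   peak_isometric_stress(ap_s2_hi))
  expect_equal(peak_isometric_stress(active_params(L_r = 1.75, L_0 = 1.58)),
               0.0554, tolerance = 1e-4)
})

test_that("duration of contraction increases with L_r and ignores L_0", {
  expect_equal(duration_of_contraction(ap), 0.611465)
  expect_equal(duration_of_contraction(active_params(L_r = 1.75, L_0 = 1.48)),
               0.506575)
  expect_equal(duration_of_contraction(active_params(L_r = 1.95, L_0 = 1.68)),
               0.716355)
  expect_identical(duration_of_contraction(active_params(L_r = 1.85, L_0 = 1.48)),
                   duration_of_contraction(active_params(L_r = 1.85, L_0 = 1.68)))
})

test_that("length-tension curve is thresholded, monotone, and consistent", {
  grid <- seq(1.4, 2.3, by = 0.01)
  lt <- length_tension_curve(grid, ap)
  expect_equal(lt$peak_tension_MPa[grid <= 1.58], rep(0, sum(grid <= 1.58)))
  expect_true(all(diff(lt$peak_tension_MPa) >= 0))
  # lowering L0 shifts the curve up at every length
  lt_lo <- length_tension_curve(grid, active_params(L_r = 1.85, L_0 = 1.48))
  expect_true(all(lt_lo$peak_tension_MPa >= lt$peak_tension_MPa))
  # value at L = L_r equals the closed-form isometric peak
  expect_equal(length_tension_curve(1.85, ap)$peak_tension_MPa,
               peak_isometric_stress(ap))
})

test_that("active parameter validation enforces the length ordering", {
  expect_error(active_params(L_r = 1.5, L_0 = 1.58), "L_r > L_0")
  expect_error(active_params(T_max = 0), "T_max")
  expect_error(active_params(L_r = 1.2, L_0 = 1.1), "relaxation")
})
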