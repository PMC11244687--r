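test_that("the %dd(10) perturbation is exactly linear with the stated coefficients", {
  g <- photon_beam_geometry()
  expect_identical(relative_dd_perturbation(g, 0, 0, 0), 0)
  expect_equal(relative_dd_perturbation(g, 0.1, 0, 0), -0.0032)
  # first-order expansion: homogeneous of degree 1 and additive
  d <- c(0.07, -0.03); s <- c(-0.1, 0.2); f <- c(0.05, 0)
  expect_equal(relative_dd_perturbation(g, 3 * d, 3 * s, 3 * f),
               3 * relative_dd_perturbation(g, d, s, f))
  expect_equal(relative_dd_perturbation(g, d, s, f),
               relative_dd_perturbation(g, d, 0, 0) +
                 relative_dd_perturbation(g, 0, s, 0) +
                 relative_dd_perturbation(g, 0, 0, f))
})

test_that("measurement coefficients derive from the scan coefficients", {
  g <- photon_beam_geometry()
  expect_equal(g$meas_depth_coeff, -0.032 - 2 / 101.5, tolerance = 1e-12)
  expect_equal(g$meas_ssd_coeff, -2 / 110, tolerance = 1e-12)
  expect_error(photon_beam_geometry(scan_depth_coeff = 0.01), "negative")
})

test_that("interim %dd(10)x formula is affine and matches pinned values", {
  expect_equal(interim_ddx(78.02), 78.85, tolerance = 5e-3)
  expect_equal(interim_ddx(70), 1.267 * 70 - 20)
  expect_equal(interim_ddx(70, 2), interim_ddx(70) + 2)
  # near-linearity: MC sigma of the interim output equals quadrature
  st1 <- random_stream(3L, "dd"); st2 <- random_stream(3L, "delta")
  dd <- draw(dist_normal(0.17, center = 78.02), 2e5, st1)
  dl <- draw(dist_uniform(half_width = 2), 2e5, st2)
  expect_equal(sd(interim_ddx(dd, dl)),
               sqrt(1.267^2 * 0.17^2 + (2 / sqrt(3))^2), tolerance = 0.01)
})

test_that("curve container validates and normalises; shifts accumulate", {
  expect_error(depth_ionization_curve(1:5, rep(1, 5)), "7 points")
  expect_error(depth_ionization_curve(c(1:6, 6), rep(1, 7)), "increasing")
  expect_error(depth_ionization_curve(1:7, c(rep(1, 6), -1)), "positive")
  cv <- depth_ionization_curve(1:10, rep(2, 10))
  expect_equal(max(cv$values), 100)

  expect_equal(shift_curve(cv, 0)$depths, cv$depths)
  cv2 <- shift_curve(shift_curve(cv, 0.15), 0.15)
  expect_equal(cv2$shift_applied, 0.30)
  expect_equal(cv2$depths, cv$depths - 0.30)
  # CC13 electron effective-point shift: half the 3 mm cavity radius
  expect_equal(shift_curve(cv, 0.5 * 0.3)$shift_applied, 0.15)
})

test_that("windowed cubic fit recovers an exact cubic's relative gradient", {
  cc <- cubic_curve()
  for (d in c(6, 8, 10)) {
    expect_equal(local_relative_gradient(cc$curve, d, window = 2),
                 cc$rel_grad(d), tolerance = 1e-9)
  }
  flat <- depth_ionization_curve(seq(0, 10, 0.5), rep(50, 21))
  expect_equal(local_relative_gradient(flat, 5, window = 1), 0,
               tolerance = 1e-12)
  expect_error(local_relative_gradient(cc$curve, 8, window = 0.3), "4 curve")
})

test_that("synthetic photon curve reproduces the 6 MV study conditions", {
  cv <- synth_curves("photon_6MV")
  g <- photon_beam_geometry()
  expect_equal(approx(cv$depths, cv$values, 10)$y, 67.74, tolerance = 0.1)
  fc <- fit_photon_coefficients(cv, g)
  expect_equal(fc$scan_depth_coeff, -0.032, tolerance = 0.05 * 0.032)
  expect_equal(fc$meas_depth_coeff, g$meas_depth_coeff,
               tolerance = 0.05 * abs(g$meas_depth_coeff))
  cv18 <- synth_curves("photon_18MV")
  expect_equal(approx(cv18$depths, cv18$values, 10)$y, 78.02, tolerance = 0.1)
})

test_that("synthetic electron curves hit the stated gradients and I50", {
  cv6 <- synth_curves("electron_6MeV")
  cv18 <- synth_curves("electron_18MeV")
  expect_equal(curve_i50(cv6), 2.40, tolerance = 0.01)
  expect_equal(curve_i50(cv18), 7.50, tolerance = 0.01)
  g6 <- electron_beam_geometry("6MeV", I50 = 2.40, curve = cv6)
  g18 <- electron_beam_geometry("18MeV", I50 = 7.50, curve = cv18)
  # about 0.8 % per mm at d_ref, within 20 %
  expect_lt(g6$gradient, -0.06)
  expect_gt(g6$gradient, -0.10)
  # dropping by about a factor 2 from 6 to 18 MeV
  expect_equal(g18$gradient / g6$gradient, 0.5, tolerance = 0.15)
})

test_that("electron geometry derives R50 and d_ref and validates I50", {
  g <- electron_beam_geometry(I50 = 2.40, gradient = -0.08)
  expect_equal(g$R50, 2.4096)
  expect_equal(g$d_ref, 1.34576)
  expect_error(electron_beam_geometry(I50 = 1.5, gradient = -0.08), "2, 10")
  expect_error(electron_beam_geometry(I50 = 5), "curve.*gradient")
})

test_that("curve CSV reader round-trips through the expected header", {
  cv <- synth_curves("electron_6MeV")
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(depth_cm = cv$depths, value = cv$values), path,
            row.names = FALSE)
  cv2 <- read_di_curve(path)
  expect_equal(cv2$depths, cv$depths)
  expect_equal(cv2$values, cv$values)
  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(x = 1:7, y = 1:7), bad, row.names = FALSE)
  expect_error(read_di_curve(bad), "depth_cm")
})
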