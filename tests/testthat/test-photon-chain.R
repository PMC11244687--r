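test_that("kQ quadratic matches the chamber fit at the pinned beam qualities", {
  # direct evaluation oracle of A + B*1e-3*x + C*1e-5*x^2 for the N30013
  quad <- function(x) 0.9652 + 2.141e-3 * x - 2.623e-5 * x^2
  expect_equal(kq(67.74), quad(67.74), tolerance = 1e-12)
  expect_equal(kq(67.74), 0.98987, tolerance = 1e-5)
  expect_equal(kq(78.85), 0.97094, tolerance = 1e-5)
  expect_equal(kq(70, 0.01, -0.002), quad(70) * 1.008, tolerance = 1e-12)
  expect_error(kq(120), "0, 100")
  expect_identical(kq_in_range(c(60, 70, 90)), c(FALSE, TRUE, FALSE))
})

test_that("temperature-pressure correction matches the closed form", {
  expect_equal(ptp(22, 760, "mmHg"), 1.0)
  expect_equal(ptp(20.7, 742.8, "mmHg"), 1.01865, tolerance = 1e-5)
  expect_equal(ptp(22, 1013.25, "mbar"), 1.0)
  expect_error(ptp(22, -5, "mbar"), "positive")
  expect_error(ptp(80, 1000, "mbar"), "plausible")
})

test_that("calibration factors scale by their relative draw", {
  expect_equal(sample_calibration_factor(1, 0), 1)
  st <- random_stream(5L, "ndw")
  d <- draw(dist_normal(0.0075), 2e5, st)
  x <- sample_calibration_factor(0.897, d)
  expect_equal(sd(x) / mean(x), 0.0075, tolerance = 0.01)
  expect_error(sample_calibration_factor(-1, 0), "positive")
})

test_that("two-voltage recombination: closed form, clamp, over-limit counts", {
  s <- protocol_settings()
  expect_equal(as.numeric(pion(1, 1, 0, s)), 1.0)
  expect_equal(as.numeric(pion(1.00299, 1, 0, s)), 1 / (2 - 1.00299),
               tolerance = 1e-9)
  # sub-unity values clamp to exactly 1 and are counted
  p <- pion(c(0.999, 1.002, 1.048), rep(1, 3), 0, s)
  expect_equal(as.numeric(p)[1], 1.0)
  expect_equal(attr(p, "clamped"), 1L)
  expect_equal(attr(p, "over_limit"), 1L)   # 1/(2-1.048) > 1.05, unclamped
  expect_gt(as.numeric(p)[3], 1.05)
  expect_error(pion(2, 1, 0, s), "singular")
})

test_that("clamp point-mass weight matches the analytic normal tail", {
  # only the formula term active: P = P0 * (1 + delta), delta ~ N(0, 0.002)
  s <- protocol_settings(P_ion_nominal = 1.003)
  n <- 2e5
  delta <- draw(dist_normal(0.002), n, random_stream(9L, "pion/formula"))
  p <- pion(rep(1.0029910269, n), rep(1, n), delta, s)
  expected <- pnorm((1 - 1.003) / (0.002 * 1.003))
  observed <- sum(as.numeric(p) == 1) / n
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(observed - expected), 5 * se)
})

test_that("polarity correction uses signed readings", {
  expect_equal(ppol(10, -10, -10), 1.0)
  expect_equal(ppol(10.05, -10, -10), 1.0025)
  expect_error(ppol(10, 10, -10), "opposite")
  expect_error(ppol(10, -10, 0), "nonzero")
})

test_that("first-order two-voltage propagation gives 2x-quadrature growth", {
  expect_equal(pion_first_order_sigma(0.0023), sqrt(2) * 0.0023)
  # scales linearly in the reading uncertainty
  expect_equal(pion_first_order_sigma(0.004), sqrt(2) * 0.004)
  expect_gt(pion_first_order_sigma(0.0023, ratio = 1.003),
            pion_first_order_sigma(0.0023))
})

test_that("nominal chain with all sigmas zero returns exactly unit dose", {
  b0 <- zero_sources(default_budget("photon"),
                     names(default_budget("photon")$sources))
  d <- suppressWarnings(run_photon(100, 1, b0))
  expect_true(all(d == 1))
  expect_equal(attr(d, "flags")$pion_clamped, 0L)
})

test_that("single-source sub-chains reproduce the published component sigmas", {
  b <- default_budget("photon")
  only <- function(keep) zero_sources(b, setdiff(names(b$sources), keep))
  # depth alone through the measurement coefficient: 0.30 %
  d <- run_photon(2e5, 1, only("depth_meas"))
  expect_equal(100 * sd(d) / mean(d), 0.30, tolerance = 0.02)
  # M_raw spread with the full set-up sources: about 0.5 %
  g <- photon_beam_geometry()
  seed <- 1
  n <- 2e5
  draws <- list(
    d_meas = draw(b$sources$depth_meas$spec, n, random_stream(seed, "m/d")),
    ssd = draw(b$sources$SSD$spec, n, random_stream(seed, "m/s")),
    field = draw(b$sources$field_size$spec, n, random_stream(seed, "m/f")),
    stability = draw(b$sources$stability$spec, n, random_stream(seed, "m/st")),
    extracameral = draw(b$sources$extracameral$spec, n,
                        random_stream(seed, "m/xc")),
    r1 = draw(b$sources$repeatability$spec, n, random_stream(seed, "m/r1")),
    r2 = draw(b$sources$repeatability$spec, n, random_stream(seed, "m/r2")),
    r3 = draw(b$sources$repeatability$spec, n, random_stream(seed, "m/r3")))
  m <- mraw_ensemble(draws, g)
  # quadrature oracle for the correlated + repeat reading spread; rounds to
  # the published "0.5 %"
  mraw_quad <- sqrt((g$meas_depth_coeff * uniform_sigma(0.1))^2 +
                    (g$meas_ssd_coeff * uniform_sigma(0.2))^2 +
                    (g$meas_field_coeff * uniform_sigma(0.2))^2 +
                    0.004^2 + 0.001^2 + 0.0004^2)
  expect_equal(sd(m$M_raw), mraw_quad, tolerance = 0.01)
  expect_equal(100 * sd(m$M_raw), 0.5, tolerance = 0.15)
  # P_pol spread comes from the two repeat draws alone: sigma_r * sqrt(2) / 2,
  # the published "0.03 %"
  pp <- ppol(m$M_plus, -m$M_raw, -m$M_raw)
  expect_equal(sd(pp), 0.0004 * sqrt(2) / 2, tolerance = 0.02)
})

test_that("the full photon run is reproducible and flags kQ range breaches", {
  sc <- cached_scenario("6MV")
  d1 <- run_scenario(sc, n = 5e4, seed = 3)
  d2 <- run_scenario(sc, n = 5e4, seed = 3)
  expect_identical(as.numeric(d1), as.numeric(d2))
  expect_equal(attr(d1, "flags")$kq_out_of_range, 0L)
  # 18 MV samples the interim formula; nominal 78.85 stays well inside (63, 86)
  d18 <- run_scenario(cached_scenario("18MV"), n = 5e4, seed = 3)
  expect_equal(attr(d18, "flags")$kq_out_of_range, 0L)
  expect_gt(attr(d18, "flags")$pion_clamped, 0L)
})

test_that("total sigma never decreases when any single source grows", {
  sc <- cached_scenario("6MV")
  sigma_with <- function(name, scale) {
    sp <- sc$budget$sources[[name]]$spec
    sp2 <- if (sp$kind == "uniform")
      dist_uniform(half_width = sp$half_width * scale, unit = sp$unit)
    else dist_normal(sp$sigma * scale, unit = sp$unit)
    b <- set_source_spec(sc$budget, name, sp2)
    100 * sd(run_scenario(sc, n = 1e5, seed = 2, budget = b))
  }
  for (name in c("pressure", "depth_meas", "chamber_calibration")) {
    sig <- vapply(c(0.5, 1, 2), function(sc_) sigma_with(name, sc_), 0)
    expect_true(all(diff(sig) > 0))
  }
})

test_that("near-linear chain: MC total agrees with per-source quadrature", {
  sc <- cached_scenario("6MV")
  ct <- contribution_table(sc, n = 2e5, seed = 1)
  full <- summarize_run(run_scenario(sc, n = 2e5, seed = 1))
  expect_equal(quadrature_total(ct), full$rel_sigma, tolerance = 0.02)
})
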