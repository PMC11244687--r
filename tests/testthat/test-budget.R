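test_that("default photon budget pins the published sigma column", {
  b <- default_budget("photon")
  sig <- function(nm) b$sources[[nm]]$spec$sigma
  hw <- function(nm) b$sources[[nm]]$spec$half_width

  expect_equal(hw("SSD"), 0.2)
  expect_equal(hw("depth_meas"), 0.1)
  expect_equal(hw("depth_scan"), 0.1)
  expect_equal(sig("temperature_A"), 0.25)
  expect_equal(sig("temperature_B"), 0.23)
  expect_equal(sig("pressure"), 4.6)
  expect_equal(hw("field_size"), 0.2)
  expect_equal(sig("kQ_intrinsic"), 0.004)
  expect_equal(sig("kQ_formula"), 0.0007)
  expect_equal(sig("repeatability"), 0.0004)
  expect_equal(sig("stability"), 0.004)
  expect_equal(sig("extracameral"), 0.001)
  expect_equal(sig("electrometer_calibration"), 0.001)
  expect_equal(sig("chamber_calibration"), 0.0075)
  expect_equal(hw("interim_formula"), 2.0)
  expect_equal(sig("pion_formula"), 0.002)
  expect_equal(hw("humidity"), 0.0015)
})

test_that("default electron budget differs where the protocol differs", {
  b <- default_budget("electron")
  expect_equal(b$sources$stability$spec$sigma, 0.003)
  expect_equal(b$sources$I50$spec$sigma, 0.087)
  expect_equal(b$sources$R50_formula$spec$half_width, 0.04)
  expect_equal(b$sources$kecal$spec$sigma, 0.005)
  expect_equal(b$sources$kprime_formula$spec$half_width, 0.002)
  expect_equal(b$sources$dset$spec$half_width, 0.1)
  expect_equal(b$sources$chamber_calibration$spec$sigma, 0.0075)
  # no photon-only sources
  expect_null(b$sources$field_size)
  expect_null(b$sources$kQ_intrinsic)
  expect_null(b$sources$interim_formula)
  expect_error(default_budget("proton"))
})

test_that("user-controlled classification matches the shaded-row convention", {
  bp <- default_budget("photon")
  up <- names(Filter(function(s) s$user_controlled, bp$sources))
  expect_setequal(up, c("SSD", "depth_meas", "depth_scan", "temperature_A",
                        "temperature_B", "pressure", "field_size"))
  be <- default_budget("electron")
  ue <- names(Filter(function(s) s$user_controlled, be$sources))
  expect_setequal(ue, c("SSD", "dset", "temperature_A", "temperature_B",
                        "pressure", "I50"))
  expect_false(be$sources$R50_formula$user_controlled)
})

test_that("zero_sources zeroes selections and leaves the original untouched", {
  b <- default_budget("photon")
  z <- zero_sources(b)  # user-controlled
  expect_equal(z$sources$SSD$spec$sigma, 0)
  expect_equal(z$sources$SSD$spec$half_width, 0)
  expect_equal(z$sources$depth_meas$spec$sigma, 0)
  expect_equal(z$sources$chamber_calibration$spec$sigma, 0.0075)
  expect_equal(b$sources$SSD$spec$half_width, 0.2)  # copy semantics

  all0 <- zero_sources(b, names(b$sources))
  expect_true(all(vapply(all0$sources, function(s) s$spec$sigma, 0) == 0))

  # group selector reaches both temperature components
  zt <- zero_sources(b, "temperature")
  expect_equal(zt$sources$temperature_A$spec$sigma, 0)
  expect_equal(zt$sources$temperature_B$spec$sigma, 0)
  expect_error(zero_sources(b, "pressur"), "pressur")
})

test_that("budget documents round-trip through YAML", {
  b <- default_budget("electron")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_budget(b, path)
  b2 <- load_budget(path)
  expect_equal(b2, b)
})

test_that("budget loader validates names, units and consistency", {
  doc_override <- '
modality: photon
inherit_defaults: true
sources:
  pressure: {distribution: uniform, sigma: 1.0, unit: mbar}
'
  b <- load_budget(doc_override)
  expect_equal(b$sources$pressure$spec$sigma, 1.0)
  # only the named source changed
  ref <- default_budget("photon")
  same <- setdiff(names(ref$sources), "pressure")
  expect_equal(b$sources[same], ref$sources[same])

  expect_error(load_budget('
modality: photon
sources:
  pressur: {distribution: uniform, sigma: 1.0, unit: mbar}
'), "pressur")
  expect_error(load_budget('
modality: photon
sources:
  pressure: {distribution: uniform, sigma: -1.0, unit: mbar}
'), "pressure")
  expect_error(load_budget('
modality: photon
sources:
  SSD: {distribution: uniform, sigma: 0.2, half_width: 0.2, unit: cm}
'), "inconsistent")
  expect_error(load_budget('
modality: photon
sources:
  SSD: {distribution: lognormal, sigma: 0.2, unit: cm}
'), "normal or uniform")
})

test_that("shipped example budget documents load", {
  for (f in c("budget_photon_6MV.yaml", "budget_electron_6MeV.yaml")) {
    p <- system.file("extdata", f, package = "tg51mc")
    skip_if(p == "", "extdata not installed")
    expect_s3_class(load_budget(p), "uncertainty_budget")
  }
})
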