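# Beam description and local sensitivity coefficients.
#
# Photon beams carry the linearised depth-dose sensitivities at the 10 cm
# reference point: the scan-curve coefficients (how %dd(10) responds to depth,
# SSD and field-size setting errors, with the depth-of-maximum shift tied to
# the depth shift) and the measurement coefficients (how the Farmer reading at
# 10 cm responds, which keeps the full inverse-square term). Electron beams
# carry the nominal I50 and the local relative gradient of the shifted
# depth-ionization curve at d_ref. Synthetic curve generators emulate
# 6 MV / 18 MV photon depth-dose curves and 6 / 18 MeV electron DI curves with
# the stated local sensitivities so the whole package tests self-contained.

#' Photon beam geometry and sensitivity coefficients
#'
#' Defaults describe a flattened 6 MV beam: SSD 100 cm, reference depth 10 cm,
#' depth of maximum 1.5 cm, 10 x 10 cm2 field (11 cm at depth),
#' %dd(10) = 67.74. The scan coefficients are the linearised response of
#' %dd(10) (depth -0.032 / cm, SSD 0.0015 / cm, field 0.010 / cm). The
#' measurement-depth coefficient for the Farmer reading restores the
#' inverse-square part that cancels in the scan ratio:
#' `meas_depth = scan_depth - 2 / (SSD + d_m)` (about -0.0517 / cm at 6 MV),
#' and `meas_SSD = -2 / (SSD + d)`.
#'
#' @param energy_label Free-text energy tag, e.g. `"6MV"`.
#' @param SSD,d,d_m,f,f_d Geometry in cm.
#' @param dd10 Nominal %dd(10) (percent of maximum).
#' @param uses_interim Logical; `TRUE` for energies above 10 MV, where
#'   %dd(10)x comes from the interim formula (see [interim_ddx()]).
#' @param scan_depth_coeff,scan_ssd_coeff,scan_field_coeff Linear response of
#'   %dd(10) (relative fraction per cm).
#' @param meas_field_coeff Field-size response of the Farmer reading
#'   (defaults to the scan value; no separate head-scatter term is modelled).
#' @return A `photon_beam_geometry`.
#' @export
photon_beam_geometry <- function(energy_label = "6MV", SSD = 100, d = 10,
                                 d_m = 1.5, f = 10, f_d = 11,
                                 dd10 = 67.74, uses_interim = FALSE,
                                 scan_depth_coeff = -0.032,
                                 scan_ssd_coeff = 0.0015,
                                 scan_field_coeff = 0.010,
                                 meas_field_coeff = scan_field_coeff) {
  if (scan_depth_coeff >= 0)
    stop("scan_depth_coeff must be negative for megavoltage photons at 10 cm",
         call. = FALSE)
  ddx <- if (uses_interim) 1.267 * dd10 - 20.0 else dd10
  if (ddx <= 63 || ddx >= 86)
    warning(sprintf("nominal %%dd(10)x = %.2f outside the kQ fit validity (63, 86)",
                    ddx))
  structure(list(
    energy_label = energy_label, SSD = SSD, d = d, d_m = d_m, f = f, f_d = f_d,
    dd10 = dd10, ddx = ddx, uses_interim = uses_interim,
    scan_depth_coeff = scan_depth_coeff, scan_ssd_coeff = scan_ssd_coeff,
    scan_field_coeff = scan_field_coeff,
    meas_depth_coeff = scan_depth_coeff - 2 / (SSD + d_m),
    meas_ssd_coeff = -2 / (SSD + d),
    meas_field_coeff = meas_field_coeff
  ), class = "photon_beam_geometry")
}

#' Relative perturbation of %dd(10) from set-up errors
#'
#' First-order expansion of the depth-dose ratio: an inverse-square SSD term,
#' a depth term (the depth-of-maximum error is taken equal to the reference
#' depth error) and a field-size term. Exactly linear in each argument.
#'
#' @param geom A [photon_beam_geometry()].
#' @param delta_d,delta_ssd,delta_f Setting errors in cm (vectors recycle).
#' @return Relative fraction (vector): `d %dd(10) / %dd(10)`.
#' @examples
#' g <- photon_beam_geometry()
#' relative_dd_perturbation(g, 0.1, 0, 0)   # -0.0032
#' @export
relative_dd_perturbation <- function(geom, delta_d, delta_ssd, delta_f) {
  geom$scan_depth_coeff * delta_d + geom$scan_ssd_coeff * delta_ssd +
    geom$scan_field_coeff * delta_f
}

#' Interim beam-quality formula for %dd(10)x
#'
#' For photon energies above 10 MV the electron-contamination-free %dd(10)x is
#' assigned from the open-beam %dd(10) by the interim formula
#' `1.267 * dd10 - 20.0`, plus a formula-error term `delta` (drawn uniform
#' +/- 2 percentage points in the default budget). Below 10 MV,
#' %dd(10)x = %dd(10) and this formula is not used.
#'
#' @param dd10 Open-beam %dd(10), percent.
#' @param delta Formula error in percentage points (default 0).
#' @return %dd(10)x, percent.
#' @examples
#' interim_ddx(78.02)   # 78.85
#' @export
interim_ddx <- function(dd10, delta = 0) 1.267 * dd10 - 20.0 + delta

#' Depth-ionization / depth-dose curve container
#'
#' Depths in cm from the water surface, strictly increasing; values are
#' normalised so the maximum reads 100 (percent scale). `shift_applied`
#' records how much upstream (toward the surface) effective-point-of-
#' measurement shift has already been applied to the depth axis.
#'
#' @param depths,values Numeric vectors (at least 7 points).
#' @param shift_applied Accumulated upstream shift, cm.
#' @return A `di_curve`.
#' @export
depth_ionization_curve <- function(depths, values, shift_applied = 0) {
  stopifnot(is.numeric(depths), is.numeric(values),
            length(depths) == length(values))
  if (length(depths) < 7)
    stop("curve needs at least 7 points", call. = FALSE)
  if (any(diff(depths) <= 0))
    stop("depths must be strictly increasing", call. = FALSE)
  if (any(values <= 0))
    stop("curve values must be positive", call. = FALSE)
  structure(list(depths = depths, values = 100 * values / max(values),
                 shift_applied = shift_applied),
            class = "di_curve")
}

#' Read a two-column depth curve from CSV
#'
#' Expects a header `depth_cm,value`.
#'
#' @param path CSV file path.
#' @param shift_applied Upstream shift already applied to the stored depths.
#' @return A [depth_ionization_curve()].
#' @export
read_di_curve <- function(path, shift_applied = 0) {
  df <- utils::read.csv(path)
  if (!all(c("depth_cm", "value") %in% names(df)))
    stop("curve CSV must have columns `depth_cm` and `value`", call. = FALSE)
  depth_ionization_curve(df$depth_cm, df$value, shift_applied)
}

#' Shift a curve upstream (effective point of measurement correction)
#'
#' Depths decrease by `shift`; the accumulated `shift_applied` increases.
#' Typical shifts: 0.6 r_cav for photon depth-dose scans, 0.5 r_cav for
#' electron depth-ionization scans (0.15 cm for a 3 mm cavity).
#'
#' @param curve A `di_curve`.
#' @param shift Non-negative shift in cm.
#' @return The shifted curve.
#' @export
shift_curve <- function(curve, shift) {
  stopifnot(inherits(curve, "di_curve"))
  if (shift < 0) stop("`shift` must be >= 0", call. = FALSE)
  curve$depths <- curve$depths - shift
  curve$shift_applied <- curve$shift_applied + shift
  curve
}

#' Local relative gradient of a curve by windowed cubic fit
#'
#' Least-squares cubic polynomial fit to the curve points within
#' `at_depth +/- window`, differentiated analytically at `at_depth`; returns
#' the relative gradient `(dV/dd) / V` in fraction per cm. On an exactly cubic
#' curve this recovers the analytic derivative to machine precision.
#'
#' @param curve A `di_curve`.
#' @param at_depth Evaluation depth, cm.
#' @param window Half-width of the fit window, cm (needs >= 4 points inside).
#' @return Relative gradient, fraction per cm.
#' @export
local_relative_gradient <- function(curve, at_depth, window = 0.8) {
  stopifnot(inherits(curve, "di_curve"))
  inside <- abs(curve$depths - at_depth) <= window
  if (sum(inside) < 4)
    stop(sprintf("need >= 4 curve points within +/- %g cm of depth %g",
                 window, at_depth), call. = FALSE)
  x <- curve$depths[inside] - at_depth  # centred for conditioning
  y <- curve$values[inside]
  fit <- stats::lm.fit(cbind(1, x, x^2, x^3), y)
  b <- fit$coefficients
  as.numeric(b[2] / b[1])  # derivative / value at x = 0
}

#' Electron beam geometry
#'
#' Holds the nominal I50, the derived nominal R50 and d_ref, and the local
#' relative gradient of the (already shifted) depth-ionization curve at d_ref,
#' either fitted from `curve` or given directly via `gradient`. The SSD
#' coefficient (default 0.02 / cm) is the inverse-square response of the
#' charge reading through the virtual source distance.
#'
#' @param energy_label Free-text tag, e.g. `"6MeV"`.
#' @param SSD Source-surface distance, cm.
#' @param I50 Nominal depth of 50 % ionization, cm (2 to 10).
#' @param curve Optional [depth_ionization_curve()] (post-shift).
#' @param gradient Optional direct relative gradient override, fraction per cm
#'   (negative beyond the ionization maximum).
#' @param ssd_coeff SSD response of the reading, fraction per cm.
#' @param window Cubic-fit half window for the gradient, cm.
#' @return An `electron_beam_geometry`.
#' @export
electron_beam_geometry <- function(energy_label = "6MeV", SSD = 100,
                                   I50 = 2.40, curve = NULL, gradient = NULL,
                                   ssd_coeff = 0.02, window = 0.8) {
  if (I50 < 2 || I50 > 10)
    stop("I50 must lie in [2, 10] cm", call. = FALSE)
  R50 <- 1.029 * I50 - 0.06
  d_ref <- 0.6 * R50 - 0.1
  if (is.null(gradient)) {
    if (is.null(curve))
      stop("give either a DI `curve` or a `gradient` override", call. = FALSE)
    gradient <- local_relative_gradient(curve, d_ref, window)
  }
  structure(list(
    energy_label = energy_label, SSD = SSD, I50 = I50, R50 = R50,
    d_ref = d_ref, gradient = gradient, ssd_coeff = ssd_coeff,
    curve = curve
  ), class = "electron_beam_geometry")
}

#' Fit photon sensitivity coefficients from a depth-dose curve
#'
#' The measurement-depth coefficient is the local relative gradient of the
#' fixed-SSD depth-dose curve at the reference depth; the scan coefficient
#' adds back the depth-of-maximum renormalisation term `+2 / (SSD + d_m)`.
#'
#' @param curve A percent-depth-dose `di_curve` at fixed SSD.
#' @param geom A [photon_beam_geometry()] providing SSD, d and d_m.
#' @param window Cubic-fit half window, cm.
#' @return List with `meas_depth_coeff` and `scan_depth_coeff` (per cm).
#' @export
fit_photon_coefficients <- function(curve, geom, window = 1.5) {
  meas <- local_relative_gradient(curve, geom$d, window)
  list(meas_depth_coeff = meas,
       scan_depth_coeff = meas + 2 / (geom$SSD + geom$d_m))
}

# --- synthetic curve generation -------------------------------------------

# Photon percent-depth-dose: inverse square times an exponential-with-
# curvature TMR surrogate, with (a, b) solved so the curve passes through the
# nominal dd(10) and the fitted scan-depth coefficient matches the target.
synth_photon_curve <- function(SSD, d_m, dd10, depth_coeff,
                               d_max_grid = 25, step = 0.05) {
  dref <- 10
  u <- dref - d_m
  # a*u + b*u^2 = 2*log((SSD+d_m)/(SSD+dref)) - log(dd10/100)
  rhs1 <- 2 * log((SSD + d_m) / (SSD + dref)) - log(dd10 / 100)
  # -(a + 2*b*u) = depth_coeff - 2/(SSD+d_m) + 2/(SSD+dref)  (log-TMR slope)
  rhs2 <- -(depth_coeff - 2 / (SSD + d_m) + 2 / (SSD + dref))
  b <- (rhs2 * u - rhs1) / u^2
  a <- rhs2 - 2 * b * u
  depths <- seq(0, d_max_grid, by = step)
  tmr <- function(d) exp(-a * (d - d_m) - b * (d - d_m)^2)
  vals <- ifelse(
    depths >= d_m,
    ((SSD + d_m) / (SSD + depths))^2 * tmr(depths),
    # smooth cosine build-up toward the maximum; realism only, the chains
    # never evaluate the curve below d_m
    0.45 + 0.55 * sin(pi / 2 * pmax(depths, 0) / d_m)
  )
  depth_ionization_curve(depths, 100 * vals / max(vals))
}

# Electron DI: a Gaussian fall-off (smooth everywhere) whose parameters are
# calibrated so the curve's I50 and the *fitted* relative gradient at d_ref
# match the requested study conditions.
synth_electron_curve <- function(I50, gradient_at_dref, window = 0.8,
                                 step = 0.05) {
  R50 <- 1.029 * I50 - 0.06
  d_ref <- 0.6 * R50 - 0.1
  g_target <- -abs(gradient_at_dref)
  # analytic start: I50 = dm + s*sqrt(2 log 2); (d_ref - dm)/s^2 = |g|
  c2 <- sqrt(2 * log(2))
  disc <- c2^2 - 4 * abs(g_target) * (I50 - d_ref)
  s0 <- if (disc > 0) (c2 - sqrt(disc)) / (2 * abs(g_target)) else 1
  dm0 <- I50 - c2 * s0
  build <- function(p) {
    dm <- p[1]; s <- exp(p[2])
    depths <- seq(0, I50 + 4 * s, by = step)
    depth_ionization_curve(depths, 100 * exp(-((depths - dm) / s)^2 / 2))
  }
  objective <- function(p) {
    cv <- build(p)
    g <- local_relative_gradient(cv, d_ref, window)
    i50 <- curve_i50(cv)
    ((i50 - I50) / 0.005)^2 + ((g - g_target) / 0.0005)^2
  }
  fit <- stats::optim(c(dm0, log(s0)), objective,
                      control = list(maxit = 400, reltol = 1e-12))
  build(fit$par)
}

#' Depth of 50 % on the falling edge of a curve
#'
#' Linear interpolation of the first crossing below 50 % beyond the maximum.
#'
#' @param curve A `di_curve`.
#' @return Depth in cm.
#' @export
curve_i50 <- function(curve) {
  imax <- which.max(curve$values)
  d <- curve$depths[imax:length(curve$depths)]
  v <- curve$values[imax:length(curve$values)]
  below <- which(v < 50)
  if (!length(below))
    stop("curve never falls below 50% beyond its maximum", call. = FALSE)
  i <- below[1]
  d[i - 1] + (50 - v[i - 1]) * (d[i] - d[i - 1]) / (v[i] - v[i - 1])
}

#' Synthetic depth curves for the four pinned beam profiles
#'
#' Deterministic fixture generator. Photon profiles are built from an
#' inverse-square times TMR-surrogate structure tuned so %dd(10) matches the
#' nominal value (67.74 for the 6 MV-like profile; 78.02 open-beam for the
#' 18 MV-like profile) and the fitted scan-depth coefficient matches
#' -0.032 / cm. Electron profiles are smooth synthetic DI curves calibrated so
#' the fitted relative gradient at d_ref is about -0.08 / cm (6 MeV-like,
#' I50 2.40 cm) and half that (-0.04 / cm, 18 MeV-like, I50 7.50 cm). The
#' curves represent the post-shift (effective point of measurement) data.
#'
#' @param profile One of `"photon_6MV"`, `"photon_18MV"`, `"electron_6MeV"`,
#'   `"electron_18MeV"`.
#' @param SSD Source-surface distance, cm.
#' @return A [depth_ionization_curve()].
#' @export
synth_curves <- function(profile = c("photon_6MV", "photon_18MV",
                                     "electron_6MeV", "electron_18MeV"),
                         SSD = 100) {
  profile <- match.arg(profile)
  switch(profile,
    photon_6MV  = synth_photon_curve(SSD, d_m = 1.5, dd10 = 67.74,
                                     depth_coeff = -0.032),
    photon_18MV = synth_photon_curve(SSD, d_m = 3.0, dd10 = 78.02,
                                     depth_coeff = -0.032),
    electron_6MeV  = synth_electron_curve(I50 = 2.40, gradient_at_dref = 0.08),
    electron_18MeV = synth_electron_curve(I50 = 7.50, gradient_at_dref = 0.04)
  )
}
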