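# Per-iteration electron calibration chain and the full electron run.
#
# The beam-quality path is I50 -> R50 -> d_ref: the same R50 draw displaces
# the reference depth (Eq-18-style sign convention: an overestimated R50
# leaves the chamber effectively shallow) *and* perturbs k'R50, preserving
# the partial cancellation between the two pathways. Depth errors convert to
# reading errors through the local relative gradient of the shifted
# depth-ionization curve at d_ref. The gradient correction P_gr never appears
# explicitly: the charge is modelled as measured once at d_ref + 0.5 r_cav,
# where it cancels exactly.

#' Electron beam-quality chain: I50 to R50 to d_ref displacement
#'
#' `I50_i = I50 + dI50`; `R50_i = 1.029 I50_i - 0.06 + dR50` (conversion
#' formula error); `d_ref displacement = 0.6 (R50_nom - R50_i) + d_set`
#' where `d_set` is the chamber depth-setting error. The nominal
#' `R50_nom = 1.029 I50 - 0.06` and `d_ref_nom = 0.6 R50_nom - 0.1`.
#'
#' @param I50_nominal Nominal depth of 50 % ionization, cm (2 to 10).
#' @param d_i50 I50 measurement error draw, cm.
#' @param d_r50_formula R50 conversion-formula error draw, cm.
#' @param d_set Chamber depth-setting error draw, cm.
#' @return List with vectors `R50_i`, `delta_dref_i` and scalars
#'   `R50_nominal`, `d_ref_nominal`.
#' @examples
#' beam_quality_chain(2.40)$d_ref_nominal  # 1.3458 cm
#' @export
beam_quality_chain <- function(I50_nominal, d_i50 = 0, d_r50_formula = 0,
                               d_set = 0) {
  if (I50_nominal < 2 || I50_nominal > 10)
    stop("I50 must lie in [2, 10] cm", call. = FALSE)
  R50_nom <- 1.029 * I50_nominal - 0.06
  R50_i <- 1.029 * (I50_nominal + d_i50) - 0.06 + d_r50_formula
  list(R50_i = R50_i,
       delta_dref_i = 0.6 * (R50_nom - R50_i) + d_set,
       R50_nominal = R50_nom,
       d_ref_nominal = 0.6 * R50_nom - 0.1)
}

#' Electron beam-quality conversion multiplier k'R50
#'
#' `k'R50 = 0.9905 + 0.071 exp(-R50 / 3.67)`, the cylindrical-chamber
#' expression valid for 2 <= R50 <= 9 cm, times `(1 + delta_formula)` for the
#' fit-formula error (uniform +/- 0.2 % in the default budget). Out-of-range
#' R50 values are accepted (callers flag them); non-positive R50 is a domain
#' error.
#'
#' @param R50 R50 in cm (vector).
#' @param delta_formula Relative formula-error draw.
#' @return k'R50 (vector).
#' @examples
#' kprime_r50(2.4096)  # 1.02732
#' kprime_r50(7.6575)  # 0.99933
#' @export
kprime_r50 <- function(R50, delta_formula = 0) {
  if (any(R50 <= 0)) stop("R50 must be positive", call. = FALSE)
  (0.9905 + 0.071 * exp(-R50 / 3.67)) * (1 + delta_formula)
}

#' Relative reading factors for one electron iteration set
#'
#' The correlated part converts the total reference-depth displacement to a
#' reading error through the DI-curve gradient, adds the SSD inverse-square
#' term (-0.02 / cm through the virtual source distance), stability and
#' extracameral current; three independent repeatability draws then build
#' M_raw, M+, M_H and M_L as for photons.
#'
#' @param draws Named list with `delta_dref` (cm), `ssd` (cm), `stability`,
#'   `extracameral`, `r1`, `r2`, `r3` (relative fractions).
#' @param geom An [electron_beam_geometry()].
#' @param settings A [protocol_settings()].
#' @return List of numeric vectors `M_raw`, `M_plus`, `M_H`, `M_L`.
#' @export
mraw_ensemble_electron <- function(draws, geom,
                                   settings = protocol_settings()) {
  corr <- geom$gradient * draws$delta_dref -
    geom$ssd_coeff * draws$ssd +
    draws$stability + draws$extracameral
  mraw_set(corr, draws$r1, draws$r2, draws$r3, settings)
}

#' Run the electron calibration chain
#'
#' Simulates `n` repetitions of the TG-51 electron calibration with a Farmer
#' chamber and returns relative doses `D_i / D_nominal`. The shared R50 draw
#' feeds both the d_ref displacement and k'R50 (their partial cancellation is
#' preserved); depth enters the reading only through the DI-curve gradient;
#' P_ion, P_pol, P_TP, calibration factors, k_ecal and humidity are handled
#' as for photons. R50 values outside the k'R50 validity range [2, 9] cm are
#' flagged, not discarded.
#'
#' @inheritParams run_photon
#' @param geom An [electron_beam_geometry()].
#' @return A `dose_samples` vector with attributes; flags count R50 validity
#'   breaches and P_ion clamp / over-limit events.
#' @export
run_electron <- function(n, seed, budget = default_budget("electron"),
                         geom, chamber = chamber_ptw_n30013(),
                         settings = protocol_settings()) {
  n <- as.integer(n)
  if (n < 1e4) warning("n < 1e4: summary statistics will be noisy")
  req <- c("SSD", "dset", "temperature_A", "temperature_B", "pressure",
           "I50", "R50_formula", "kecal", "kprime_formula", "repeatability",
           "stability", "extracameral", "electrometer_calibration",
           "chamber_calibration", "pion_formula", "humidity")
  validate_budget(budget, req)
  g <- function(name, sub = NULL) bdraw(budget, name, n, seed, sub)

  d_ssd <- g("SSD")
  t_a <- g("temperature_A"); t_b <- g("temperature_B"); d_p <- g("pressure")

  # beam-quality path (shared R50 draw -> d_ref displacement and k'R50)
  bq <- beam_quality_chain(geom$I50, g("I50"), g("R50_formula"), g("dset"))
  kprime_i <- kprime_r50(bq$R50_i, g("kprime_formula"))
  kprime_nom <- kprime_r50(bq$R50_nominal)
  kecal_i <- sample_calibration_factor(chamber$k_ecal, g("kecal"))

  ptp_i <- ptp(settings$T0 + t_a + t_b, settings$p0 + d_p,
               settings$pressure_unit)
  ptp_nom <- ptp(settings$T0, settings$p0, settings$pressure_unit)

  m <- mraw_ensemble_electron(
    list(delta_dref = bq$delta_dref_i, ssd = d_ssd,
         stability = g("stability"), extracameral = g("extracameral"),
         r1 = g("repeatability", "1"), r2 = g("repeatability", "2"),
         r3 = g("repeatability", "3")),
    geom, settings)
  ppol_i <- ppol(m$M_plus, -m$M_raw, -m$M_raw)
  pion_i <- pion(m$M_H, m$M_L, g("pion_formula"), settings)

  dose_i <- m$M_raw * pion_i * ptp_i * ppol_i * kprime_i * kecal_i *
    (1 + g("chamber_calibration")) * (1 + g("electrometer_calibration")) *
    (1 + g("humidity"))
  dose_nom <- 1 * settings$P_ion_nominal * ptp_nom *
    settings$P_pol_nominal * kprime_nom * chamber$k_ecal

  structure(dose_i / dose_nom, class = "dose_samples",
            modality = "electron", seed = as.integer(seed), n = n,
            flags = list(r50_out_of_range = sum(bq$R50_i < 2 | bq$R50_i > 9),
                         pion_clamped = attr(pion_i, "clamped"),
                         pion_over_limit = attr(pion_i, "over_limit")))
}
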