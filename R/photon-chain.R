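# Per-iteration photon calibration chain and the full photon run.
#
# Each Monte Carlo iteration perturbs every budget source once and pushes the
# perturbations through the TG-51 worksheet: scan depth/SSD/field -> %dd(10)
# -> %dd(10)x (interim formula above 10 MV) -> kQ; temperature/pressure ->
# P_TP; correlated charge-reading errors plus independent repeatability draws
# -> M_raw, M+, M_H, M_L -> P_pol and the two-voltage P_ion; calibration
# factors and humidity multiply in. The returned samples are relative doses
# D_i / D_nominal, so every absolute scale (N_D,w, MU, electrometer gain)
# cancels and only the perturbations matter.

#' Ion chamber constants (PTW N30013 Farmer type)
#'
#' kQ fit constants `A + B*1e-3*ddx + C*1e-5*ddx^2` for the PTW N30013
#' (A = 0.9652, B = 2.141, C = -2.623, valid for 63 < %dd(10)x < 86), cavity
#' radius, and the relative uncertainties of the ADCL calibration factor and
#' electrometer gain. `k_ecal` is the chamber's electron conversion factor at
#' the reference beam quality; its nominal value is user-supplied bookkeeping
#' (it cancels in the relative dose) — only its 0.5 % relative uncertainty
#' enters the electron budget.
#'
#' @param A,B,C kQ quadratic fit constants.
#' @param r_cav Cavity radius, cm.
#' @param N_Dw_rel_u Relative (k = 1) uncertainty of the calibration factor.
#' @param P_elec_nominal,P_elec_rel_u Electrometer correction and its
#'   relative uncertainty.
#' @param k_ecal Nominal electron conversion factor.
#' @param model_name Chamber model tag.
#' @return A `chamber_spec`.
#' @export
chamber_ptw_n30013 <- function(A = 0.9652, B = 2.141, C = -2.623,
                               r_cav = 0.305, N_Dw_rel_u = 0.0075,
                               P_elec_nominal = 1.000, P_elec_rel_u = 0.001,
                               k_ecal = 0.897, model_name = "PTW N30013") {
  structure(list(A = A, B = B, C = C, r_cav = r_cav,
                 N_Dw_rel_u = N_Dw_rel_u, P_elec_nominal = P_elec_nominal,
                 P_elec_rel_u = P_elec_rel_u, k_ecal = k_ecal,
                 model_name = model_name),
            class = "chamber_spec")
}

#' Protocol settings for a calibration session
#'
#' @param P_ion_nominal Nominal two-voltage recombination correction. The
#'   protocol requires 1.00 <= P_ion < 1.05; the default 1.003 is a typical
#'   Farmer-chamber value at reference conditions (a specific chamber's value
#'   should be set from measurement).
#' @param P_pol_nominal Nominal polarity correction (1.000: no polarity
#'   asymmetry is modelled).
#' @param T0 Water temperature reading, degrees C.
#' @param p0 Pressure reading, in `pressure_unit`.
#' @param pressure_unit `"mbar"` (reference 1013.25) or `"mmHg"`
#'   (reference 760).
#' @param voltage_ratio High/low bias ratio for the two-voltage method
#'   (exactly 2).
#' @param MU Monitor units per irradiation.
#' @return A `protocol_settings`.
#' @export
protocol_settings <- function(P_ion_nominal = 1.003, P_pol_nominal = 1.000,
                              T0 = 20.7, p0 = 990.1,
                              pressure_unit = c("mbar", "mmHg"),
                              voltage_ratio = 2, MU = 100) {
  pressure_unit <- match.arg(pressure_unit)
  if (P_ion_nominal < 1.00 || P_ion_nominal >= 1.05)
    stop("P_ion_nominal must satisfy 1.00 <= P_ion < 1.05", call. = FALSE)
  if (voltage_ratio != 2)
    stop("the two-voltage implementation assumes V_H / V_L = 2 exactly",
         call. = FALSE)
  structure(list(P_ion_nominal = P_ion_nominal,
                 P_pol_nominal = P_pol_nominal, T0 = T0, p0 = p0,
                 pressure_unit = pressure_unit,
                 voltage_ratio = voltage_ratio, MU = MU),
            class = "protocol_settings")
}

#' Beam-quality conversion factor kQ
#'
#' Quadratic chamber fit evaluated at %dd(10)x, with relative intrinsic and
#' fit-formula perturbations applied multiplicatively. Values of `ddx`
#' outside (63, 86) are outside the fit's stated validity; callers flag (not
#' discard) such samples.
#'
#' @param ddx %dd(10)x, percent (vector).
#' @param delta0 Relative intrinsic perturbation (normal, sigma 0.004).
#' @param delta_fit Relative fit-formula perturbation (normal, sigma 0.0007).
#' @param chamber A [chamber_ptw_n30013()]-style spec.
#' @return kQ (vector).
#' @examples
#' kq(67.74)  # 0.98987 for the PTW N30013
#' @export
kq <- function(ddx, delta0 = 0, delta_fit = 0,
               chamber = chamber_ptw_n30013()) {
  if (any(ddx < 0 | ddx > 100))
    stop("%dd(10)x outside [0, 100]", call. = FALSE)
  base <- chamber$A + chamber$B * 1e-3 * ddx + chamber$C * 1e-5 * ddx^2
  base * (1 + delta0 + delta_fit)
}

kq_in_range <- function(ddx) ddx > 63 & ddx < 86

#' Temperature-pressure air density correction
#'
#' `P_TP = (p_ref / p) * ((273.2 + T) / 295.2)` with the reference pressure in
#' the caller's declared unit (760 mmHg or 1013.25 mbar).
#'
#' @param T_c Temperature, degrees C (0 to 50).
#' @param p Pressure in `unit`.
#' @param unit `"mbar"` or `"mmHg"`.
#' @return P_TP (vector).
#' @examples
#' ptp(22, 760, "mmHg")     # 1 at reference conditions
#' ptp(20.7, 742.8, "mmHg") # 1.01865
#' @export
ptp <- function(T_c, p, unit = c("mbar", "mmHg")) {
  unit <- match.arg(unit)
  if (any(p <= 0)) stop("pressure must be positive", call. = FALSE)
  if (any(T_c < 0 | T_c > 50))
    stop("temperature outside the plausible 0-50 degC range", call. = FALSE)
  p_ref <- if (unit == "mmHg") 760 else 1013.25
  (p_ref / p) * ((273.2 + T_c) / 295.2)
}

#' Scale a calibration factor by a relative draw
#'
#' `nominal * (1 + rel_draw)`: used for N_D,w, P_elec and k_ecal.
#'
#' @param nominal Positive nominal value.
#' @param rel_draw Relative perturbation (vector).
#' @return Perturbed factor (vector).
#' @export
sample_calibration_factor <- function(nominal, rel_draw) {
  if (any(nominal <= 0)) stop("nominal must be positive", call. = FALSE)
  nominal * (1 + rel_draw)
}

#' Two-voltage recombination correction
#'
#' `P_ion = -1 / (M_H / M_L - 2) + delta_formula * P_ion_nominal`, assuming a
#' voltage ratio of exactly 2. Computed values below 1.000 are clamped to
#' 1.000 (the physical constraint; this piles a point mass at exactly 1);
#' values above 1.05 (chamber unusable under the protocol) are counted but
#' not altered. Clamp and over-limit counts are attached as attributes.
#'
#' @param M_H,M_L High- and low-voltage readings (vectors).
#' @param delta_formula Relative formula-error draw.
#' @param settings A [protocol_settings()].
#' @return P_ion vector with attributes `clamped` and `over_limit`.
#' @export
pion <- function(M_H, M_L, delta_formula = 0,
                 settings = protocol_settings()) {
  if (any(M_L == 0)) stop("M_L must be nonzero", call. = FALSE)
  r <- M_H / M_L
  if (any(abs(r - 2) < 1e-12))
    stop("two-voltage formula singular at M_H / M_L = 2", call. = FALSE)
  p <- -1 / (r - 2) + delta_formula * settings$P_ion_nominal
  clamped <- sum(p < 1)
  over <- sum(p > 1.05)
  p[p < 1] <- 1
  structure(p, clamped = clamped, over_limit = over)
}

#' Polarity correction
#'
#' `|(M_plus - M_minus) / (2 M)|` with signed readings (negative charge is
#' collected at the calibration polarity).
#'
#' @param M_plus,M_minus Signed readings at the two polarities.
#' @param M Signed reading at the calibration polarity.
#' @return P_pol (vector).
#' @examples
#' ppol(10, -10, -10)      # 1
#' ppol(10.05, -10, -10)   # 1.0025
#' @export
ppol <- function(M_plus, M_minus, M) {
  if (any(M == 0)) stop("M must be nonzero", call. = FALSE)
  if (any(sign(M_plus) == sign(M_minus)))
    stop("M_plus and M_minus must have opposite signs", call. = FALSE)
  abs((M_plus - M_minus) / (2 * M))
}

#' First-order relative uncertainty of P_ion from reading noise
#'
#' Gaussian quadrature propagation of independent, equal relative reading
#' uncertainties through the two-voltage formula
#' `P_ion = (1 - V_H/V_L) / (M_H/M_L - V_H/V_L)` at voltage ratio 2:
#' `sigma_P / P = sqrt(2) * u * r / (2 - r)` with `r = M_H / M_L`.
#'
#' @param rel_u Relative (k = 1) uncertainty of each reading (e.g. 0.0023).
#' @param ratio Reading ratio `M_H / M_L` (default 1: readings nearly equal).
#' @return Relative uncertainty of P_ion (fraction).
#' @examples
#' pion_first_order_sigma(0.0023)  # 0.00325, i.e. 0.33 %
#' @export
pion_first_order_sigma <- function(rel_u, ratio = 1) {
  sqrt(2) * rel_u * ratio / (2 - ratio)
}

# Draw from a budget source through its labelled stream. `sub` separates the
# independent repeatability draws of the three charge readings.
bdraw <- function(budget, name, n, seed, sub = NULL) {
  src <- budget$sources[[name]]
  if (is.null(src))
    stop("budget has no source `", name, "`", call. = FALSE)
  label <- paste(c(budget$modality, name, sub), collapse = "/")
  draw(src$spec, n, random_stream(seed, label))
}

# Correlated + repeatability charge model shared by both chains: returns the
# four relative reading factors. `corr` is the per-iteration correlated part
# (set-up, stability, extracameral). The low-voltage nominal is fixed so that
# the nominal reading ratio reproduces P_ion_nominal.
mraw_set <- function(corr, r1, r2, r3, settings) {
  ML0 <- 1 / (2 - 1 / settings$P_ion_nominal)
  list(M_raw = 1 + corr + r1,
       M_plus = 1 + corr + r2,       # magnitude; sign handled in ppol call
       M_H = 1 + corr + r1,          # M_H == M_raw == M_minus in this scheme
       M_L = ML0 * (1 + corr + r3))
}

#' Relative reading factors for one photon iteration set
#'
#' Builds M_raw, M+, M_H and M_L from the correlated set-up part (depth, SSD
#' and field-size terms at the measurement point, stability, extracameral)
#' plus three independent repeatability draws. All absolute scales are
#' normalised out: the nominal reading is 1.
#'
#' @param draws Named list with elements `d_meas`, `ssd`, `field` (cm),
#'   `stability`, `extracameral`, `r1`, `r2`, `r3` (relative fractions).
#' @param geom A [photon_beam_geometry()].
#' @param settings A [protocol_settings()].
#' @return List of numeric vectors `M_raw`, `M_plus`, `M_H`, `M_L`.
#' @export
mraw_ensemble <- function(draws, geom, settings = protocol_settings()) {
  corr <- geom$meas_depth_coeff * draws$d_meas +
    geom$meas_ssd_coeff * draws$ssd +
    geom$meas_field_coeff * draws$field +
    draws$stability + draws$extracameral
  mraw_set(corr, draws$r1, draws$r2, draws$r3, settings)
}

#' Run the photon calibration chain
#'
#' Simulates `n` independent repetitions of the TG-51 photon calibration with
#' every budget source perturbed, and returns the relative doses
#' `D_i / D_nominal`. The %dd(10) scan perturbation feeds the kQ quadratic
#' (through the interim formula when `geom$uses_interim`); temperature and
#' pressure feed P_TP; the charge model feeds M_raw, P_pol and the clamped
#' two-voltage P_ion; calibration-factor, stability, extracameral and humidity
#' terms multiply in. Iterations with %dd(10)x outside the kQ fit validity
#' are flagged, not discarded.
#'
#' @param n Number of iterations (at least 1e4 recommended for summaries).
#' @param seed Integer run seed; every source draws from its own labelled
#'   stream derived from this seed.
#' @param budget An `uncertainty_budget` (photon).
#' @param geom A [photon_beam_geometry()].
#' @param chamber A [chamber_ptw_n30013()]-style spec.
#' @param settings A [protocol_settings()].
#' @return Numeric vector of relative doses with class `dose_samples` and
#'   attributes `modality`, `seed`, `flags` (kQ validity breaches, P_ion
#'   clamp and over-limit counts).
#' @export
run_photon <- function(n, seed, budget = default_budget("photon"),
                       geom = photon_beam_geometry(),
                       chamber = chamber_ptw_n30013(),
                       settings = protocol_settings()) {
  n <- as.integer(n)
  if (n < 1e4) warning("n < 1e4: summary statistics will be noisy")
  req <- c("SSD", "depth_meas", "depth_scan", "temperature_A",
           "temperature_B", "pressure", "field_size", "kQ_intrinsic",
           "kQ_formula", "repeatability", "stability", "extracameral",
           "electrometer_calibration", "chamber_calibration", "pion_formula",
           "humidity")
  if (geom$uses_interim) req <- c(req, "interim_formula")
  validate_budget(budget, req)
  g <- function(name, sub = NULL) bdraw(budget, name, n, seed, sub)

  d_scan <- g("depth_scan"); d_meas <- g("depth_meas")
  d_ssd <- g("SSD"); d_f <- g("field_size")
  t_a <- g("temperature_A"); t_b <- g("temperature_B"); d_p <- g("pressure")

  # beam quality path
  dd_rel <- relative_dd_perturbation(geom, d_scan, d_ssd, d_f)
  dd10_i <- geom$dd10 * (1 + dd_rel)
  ddx_i <- if (geom$uses_interim)
    interim_ddx(dd10_i, g("interim_formula")) else dd10_i
  kq_i <- kq(ddx_i, g("kQ_intrinsic"), g("kQ_formula"), chamber)
  kq_nom <- kq(geom$ddx, 0, 0, chamber)

  # environmental path
  ptp_i <- ptp(settings$T0 + t_a + t_b, settings$p0 + d_p,
               settings$pressure_unit)
  ptp_nom <- ptp(settings$T0, settings$p0, settings$pressure_unit)

  # charge path
  m <- mraw_ensemble(
    list(d_meas = d_meas, ssd = d_ssd, field = d_f,
         stability = g("stability"), extracameral = g("extracameral"),
         r1 = g("repeatability", "1"), r2 = g("repeatability", "2"),
         r3 = g("repeatability", "3")),
    geom, settings)
  ppol_i <- ppol(m$M_plus, -m$M_raw, -m$M_raw)
  pion_i <- pion(m$M_H, m$M_L, g("pion_formula"), settings)

  dose_i <- m$M_raw * pion_i * ptp_i * ppol_i * kq_i *
    (1 + g("chamber_calibration")) * (1 + g("electrometer_calibration")) *
    (1 + g("humidity"))
  dose_nom <- 1 * settings$P_ion_nominal * ptp_nom *
    settings$P_pol_nominal * kq_nom

  structure(dose_i / dose_nom, class = "dose_samples",
            modality = "photon", seed = as.integer(seed), n = n,
            flags = list(kq_out_of_range = sum(!kq_in_range(ddx_i)),
                         pion_clamped = attr(pion_i, "clamped"),
                         pion_over_limit = attr(pion_i, "over_limit")))
}
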