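# Summary statistics, expanded uncertainty, contribution decomposition against
# the quadrature oracle, sensitivity sweeps, audit tail probabilities and
# normality diagnostics.

sample_skewness <- function(x) {
  m <- mean(x); s <- stats::sd(x)
  mean((x - m)^3) / s^3
}

sample_excess_kurtosis <- function(x) {
  m <- mean(x); s <- stats::sd(x)
  mean((x - m)^4) / s^4 - 3
}

#' Summarise a run of relative dose samples
#'
#' Reduces the samples to the k = 1 relative standard deviation (percent),
#' the k = 2 expanded interval (exactly `2 * rel_sigma`, the conventional
#' "95 % CI" arithmetic), the 1.96-sigma interval and the empirical
#' 2.5th-97.5th percentile half width for comparison, plus shape diagnostics
#' and the flag counts recorded by the run.
#'
#' @param samples A `dose_samples` vector (or any numeric vector, n >= 100).
#' @return A `sim_summary` list.
#' @export
summarize_run <- function(samples) {
  x <- as.numeric(samples)
  if (length(x) < 100) stop("need at least 100 samples", call. = FALSE)
  m <- mean(x)
  rel_sigma <- 100 * stats::sd(x) / m
  q <- stats::quantile(x, c(0.025, 0.975), names = FALSE)
  structure(list(
    n = length(x),
    mean = m,
    rel_sigma = rel_sigma,
    expanded_95 = 2 * rel_sigma,
    interval_196 = 1.96 * rel_sigma,
    empirical_95_half = 100 * (q[2] - q[1]) / (2 * m),
    skewness = sample_skewness(x),
    excess_kurtosis = sample_excess_kurtosis(x),
    flags = attr(samples, "flags"),
    modality = attr(samples, "modality"),
    seed = attr(samples, "seed")
  ), class = "sim_summary")
}

#' @export
print.sim_summary <- function(x, ...) {
  cat(sprintf("<sim_summary%s: n = %d>\n",
              if (!is.null(x$modality)) paste0(" ", x$modality) else "", x$n))
  cat(sprintf("  relative sigma (k=1)   %.3f %%\n", x$rel_sigma))
  cat(sprintf("  expanded (k=2)         %.3f %%\n", x$expanded_95))
  cat(sprintf("  empirical 95%% half     %.3f %%\n", x$empirical_95_half))
  cat(sprintf("  skewness %.4f, excess kurtosis %.4f\n",
              x$skewness, x$excess_kurtosis))
  if (!is.null(x$flags) && length(x$flags))
    cat("  flags:", paste(names(x$flags), unlist(x$flags), sep = " = ",
                          collapse = ", "), "\n")
  invisible(x)
}

#' Per-source contribution to the dose uncertainty
#'
#' One row per source group with nonzero sigma: the run is repeated with all
#' *other* sources zeroed, and the resulting relative dose sigma is that
#' group's contribution. The two temperature components form one group.
#' Contribution runs reuse the same per-source stream seeds as the full run,
#' so the decomposition is seed-stable.
#'
#' @param scenario A [build_scenario()] result (or compatible list).
#' @param n Iterations per contribution run.
#' @param seed Run seed.
#' @return A data frame with columns `source`, `assigned_sigma`, `unit`,
#'   `user_controlled`, `contribution_pct`.
#' @export
contribution_table <- function(scenario, n = 3e5, seed = 1L) {
  b <- scenario$budget
  active <- Filter(function(s) s$spec$sigma > 0, b$sources)
  groups <- unique(vapply(active, `[[`, "", "group"))
  rows <- lapply(groups, function(gr) {
    members <- names(Filter(function(s) s$group == gr, b$sources))
    others <- setdiff(names(b$sources), members)
    b1 <- if (length(others)) zero_sources(b, others) else b
    s <- summarize_run(run_scenario(scenario, n = n, seed = seed,
                                    budget = b1))
    first <- b$sources[[members[1]]]
    data.frame(
      source = gr,
      assigned_sigma = paste(
        vapply(members,
               function(nm) sprintf("%g", b$sources[[nm]]$spec$sigma), ""),
        collapse = " + "),
      unit = first$spec$unit,
      user_controlled = first$user_controlled,
      contribution_pct = s$rel_sigma,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Root-sum-square of contribution rows
#'
#' The Gaussian quadrature oracle for uncorrelated, near-linear sources: the
#' total relative sigma is the root sum of squares of the per-source
#' contributions. Used to cross-check the full Monte Carlo total.
#'
#' @param rows Numeric vector of contributions in percent, or a
#'   [contribution_table()] data frame.
#' @return Root-sum-square total, percent.
#' @export
quadrature_total <- function(rows) {
  x <- if (is.data.frame(rows)) rows$contribution_pct else as.numeric(rows)
  if (!length(x)) stop("no contributions supplied", call. = FALSE)
  sqrt(sum(x^2))
}

#' Sensitivity sweep of one user-controlled source
#'
#' For each grid half-width: every other user-controlled source is zeroed,
#' non-user sources keep their budget values, and the swept source is sampled
#' uniformly with that half-width. The value at half-width 0 is the
#' out-of-user-control uncertainty floor. Streams are label-stable across the
#' grid, so the swept source's draws scale continuously with the half-width
#' and the curve is smooth in the Monte Carlo noise.
#'
#' @param scenario A [build_scenario()] result.
#' @param source Name of a user-controlled source (e.g. `"depth_meas"`,
#'   `"SSD"`, `"field_size"`, `"dset"`, `"I50"`).
#' @param half_widths_mm Grid of half-widths in mm (default 0 to 2 by 0.25).
#' @param n Iterations per grid point.
#' @param seed Run seed.
#' @return A `sweep_curve` data frame: `half_width_mm`, `rel_sigma_pct`.
#' @export
sensitivity_sweep <- function(scenario, source,
                              half_widths_mm = seq(0, 2, by = 0.25),
                              n = 2e5, seed = 1L) {
  b <- scenario$budget
  src <- b$sources[[source]]
  if (is.null(src)) stop("unknown source: ", source, call. = FALSE)
  if (!src$user_controlled)
    stop("`", source, "` is not user-controlled", call. = FALSE)
  if (is.unsorted(half_widths_mm, strictly = TRUE))
    stop("half-width grid must be strictly increasing", call. = FALSE)
  user <- names(Filter(function(s) s$user_controlled, b$sources))
  base <- zero_sources(b, user)
  rel <- vapply(half_widths_mm, function(hw) {
    bi <- set_source_spec(base, source,
                          dist_uniform(half_width = hw / 10,
                                       unit = src$spec$unit))
    summarize_run(run_scenario(scenario, n = n, seed = seed,
                               budget = bi))$rel_sigma
  }, 0)
  structure(data.frame(half_width_mm = half_widths_mm, rel_sigma_pct = rel),
            class = c("sweep_curve", "data.frame"),
            source = source, scenario_id = scenario$id)
}

#' @export
plot.sweep_curve <- function(x, ...) {
  graphics::plot(x$half_width_mm, x$rel_sigma_pct, type = "b", pch = 16,
                 xlab = "half width (mm)",
                 ylab = "relative dose sigma (%)",
                 main = sprintf("Sweep of %s (%s)", attr(x, "source"),
                                attr(x, "scenario_id") %||% ""), ...)
  invisible(x)
}

#' Probability that a dose (or dose ratio) falls outside a tolerance
#'
#' For independent Gaussian calibration and audit uncertainties, the ratio of
#' the two doses has sigma `sqrt(sigma_cal^2 + sigma_audit^2)` and the
#' two-sided tail beyond `+/- tolerance` is
#' `2 * Phi(-tolerance / sigma_combined)`. With `sigma_audit = 0` this is the
#' calibration-only tail.
#'
#' @param sigma_cal Calibration relative sigma, percent.
#' @param sigma_audit Audit (e.g. OSLD) relative sigma, percent.
#' @param tolerance Tolerance, percent (e.g. 5).
#' @return Probability (0 to 1).
#' @examples
#' out_of_tolerance_probability(1.15, 1.7, 5)  # about 0.015
#' @export
out_of_tolerance_probability <- function(sigma_cal, sigma_audit = 0,
                                         tolerance = 5) {
  if (sigma_cal < 0 || sigma_audit < 0 || tolerance <= 0)
    stop("sigmas must be >= 0 and tolerance > 0", call. = FALSE)
  s <- sqrt(sigma_cal^2 + sigma_audit^2)
  if (s == 0) return(0)
  2 * stats::pnorm(-tolerance / s)
}

#' Normality diagnostics of a dose sample distribution
#'
#' Histogram bin counts with the matched-normal expected counts, skewness and
#' excess kurtosis, and a chi-square goodness statistic. No pass/fail is
#' hard-coded; the caller judges.
#'
#' @param samples Numeric vector, n >= 1e4.
#' @param bins Number of histogram bins.
#' @return A list with `breaks`, `counts`, `expected`, `skewness`,
#'   `excess_kurtosis`, `chi_square`, `df`.
#' @export
normality_report <- function(samples, bins = 60) {
  x <- as.numeric(samples)
  if (length(x) < 1e4) stop("need at least 1e4 samples", call. = FALSE)
  m <- mean(x); s <- stats::sd(x)
  breaks <- seq(min(x), max(x), length.out = bins + 1)
  breaks[1] <- breaks[1] - 1e-12
  counts <- graphics::hist(x, breaks = breaks, plot = FALSE)$counts
  p <- diff(stats::pnorm(breaks, m, s))
  expected <- length(x) * p / sum(p)
  keep <- expected >= 5
  chi_sq <- sum((counts[keep] - expected[keep])^2 / expected[keep])
  list(breaks = breaks, counts = counts, expected = expected,
       skewness = sample_skewness(x),
       excess_kurtosis = sample_excess_kurtosis(x),
       chi_square = chi_sq, df = sum(keep) - 3)
}

#' Component standard deviations of intermediate chain quantities
#'
#' Recomputes, with the scenario's budget and the same labelled streams as
#' the full run, the relative sigma of a single sub-chain: the
#' temperature-pressure correction (`"ptp"`), the %dd(10) scan perturbation
#' (`"dd10"`), or the full sampled kQ (`"kq"`, photon scenarios only).
#'
#' @param scenario A [build_scenario()] result.
#' @param component `"ptp"`, `"dd10"` or `"kq"`.
#' @param n Iterations.
#' @param seed Run seed.
#' @return Relative sigma in percent.
#' @export
component_sigma <- function(scenario, component = c("ptp", "dd10", "kq"),
                            n = 1e6, seed = 1L) {
  component <- match.arg(component)
  b <- scenario$budget
  st <- scenario$settings
  g <- function(name, sub = NULL) bdraw(b, name, n, seed, sub)
  if (component == "ptp") {
    v <- ptp(st$T0 + g("temperature_A") + g("temperature_B"),
             st$p0 + g("pressure"), st$pressure_unit)
    return(100 * stats::sd(v) / mean(v))
  }
  geom <- scenario$geom
  if (is.null(geom$dd10))
    stop("component `", component, "` needs a photon scenario", call. = FALSE)
  dd_rel <- relative_dd_perturbation(geom, g("depth_scan"), g("SSD"),
                                     g("field_size"))
  if (component == "dd10") return(100 * stats::sd(dd_rel))
  dd10_i <- geom$dd10 * (1 + dd_rel)
  ddx_i <- if (geom$uses_interim)
    interim_ddx(dd10_i, g("interim_formula")) else dd10_i
  v <- kq(ddx_i, g("kQ_intrinsic"), g("kQ_formula"), scenario$chamber)
  100 * stats::sd(v) / mean(v)
}
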