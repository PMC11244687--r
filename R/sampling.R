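# Random-draw primitives: the two sampling laws used throughout the chains
# (untruncated normal, bounded uniform), the uniform-sigma relation, and
# labelled independent sub-streams so that adding or zeroing one uncertainty
# source never perturbs the draws of another.

#' Standard deviation of a bounded uniform distribution
#'
#' For a uniform distribution on `[-half_width, +half_width]` the standard
#' deviation is `half_width / sqrt(3)`.
#'
#' @param half_width Non-negative half range, in the unit of the quantity.
#' @return The standard deviation, same unit as `half_width`.
#' @examples
#' uniform_sigma(0.2)   # 0.1155 cm for a +/- 2 mm setting tolerance
#' uniform_sigma(8)     # 4.62 mbar for a +/- 8 mbar barometer
#' @export
uniform_sigma <- function(half_width) {
  if (!is.numeric(half_width) || any(half_width < 0))
    stop("`half_width` must be non-negative", call. = FALSE)
  half_width / sqrt(3)
}

new_dist_spec <- function(kind, sigma, half_width, center, unit) {
  structure(
    list(kind = kind, sigma = sigma, half_width = half_width,
         center = center, unit = unit),
    class = "dist_spec"
  )
}

#' Distribution specification for an uncertainty source
#'
#' `dist_normal()` describes an untruncated Gaussian perturbation;
#' `dist_uniform()` a bounded uniform perturbation. For the uniform law,
#' either the half width or the standard deviation may be given; the other is
#' derived via `sigma = half_width / sqrt(3)`. Supplying both inconsistently
#' is a configuration error.
#'
#' @param sigma Standard deviation (unit of the quantity, or a dimensionless
#'   relative fraction).
#' @param half_width Half range of the uniform law (same unit as `sigma`).
#' @param center Offset added to every draw (default 0).
#' @param unit Free-text unit label carried for validation and display.
#' @return A `dist_spec` object.
#' @examples
#' dist_uniform(half_width = 0.2, unit = "cm")  # SSD setting, +/- 2 mm
#' dist_normal(sigma = 0.004)                   # kQ intrinsic, 0.4 % relative
#' @export
dist_normal <- function(sigma, center = 0, unit = "relative") {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0)
    stop("normal `sigma` must be a single non-negative number", call. = FALSE)
  new_dist_spec("normal", sigma, NA_real_, center, unit)
}

#' @rdname dist_normal
#' @export
dist_uniform <- function(half_width = NULL, sigma = NULL, center = 0,
                         unit = "relative") {
  if (is.null(half_width) && is.null(sigma))
    stop("give `half_width` or `sigma` for a uniform spec", call. = FALSE)
  if (!is.null(half_width)) {
    if (half_width < 0) stop("`half_width` must be non-negative", call. = FALSE)
    derived <- uniform_sigma(half_width)
    if (!is.null(sigma) &&
        abs(sigma - derived) > 1e-9 * max(1, abs(derived)))
      stop("inconsistent uniform spec: sigma != half_width / sqrt(3)",
           call. = FALSE)
    sigma <- derived
  } else {
    if (sigma < 0) stop("`sigma` must be non-negative", call. = FALSE)
    half_width <- sigma * sqrt(3)
  }
  new_dist_spec("uniform", sigma, half_width, center, unit)
}

#' @export
print.dist_spec <- function(x, ...) {
  if (x$kind == "uniform") {
    cat(sprintf("uniform(+/- %g %s, sigma = %g)\n",
                x$half_width, x$unit, x$sigma))
  } else {
    cat(sprintf("normal(sigma = %g %s)\n", x$sigma, x$unit))
  }
  invisible(x)
}

#' Labelled reproducible random stream
#'
#' One independent stream per uncertainty source per run: the stream seed is
#' derived deterministically from the run seed and a text label, so identical
#' `(seed, label)` pairs reproduce bit-identical draw sequences and distinct
#' labels give statistically independent sequences. Adding, removing or
#' zeroing one source therefore never changes another source's draws.
#'
#' @param seed Integer run seed.
#' @param label Stream label, conventionally `"<modality>/<source>"`.
#' @return A `random_stream` object.
#' @export
random_stream <- function(seed, label) {
  stopifnot(is.character(label), length(label) == 1L)
  seed <- as.integer(seed)
  if (is.na(seed)) stop("`seed` must be an integer", call. = FALSE)
  structure(list(seed = seed, label = label), class = "random_stream")
}

# 31-ary rolling hash of the label folded with the run seed; kept below 2^31.
stream_seed <- function(stream) {
  h <- 0
  for (code in utf8ToInt(stream$label)) h <- (h * 31 + code) %% 2147480009
  as.integer((h + (as.double(stream$seed) %% 2147480009) * 48271) %% 2147483629)
}

with_stream <- function(stream, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stream_seed(stream))
  expr
}

#' Draw from a distribution specification
#'
#' Normal specs give i.i.d. Gaussian draws about `center`; uniform specs give
#' i.i.d. draws on `[center - half_width, center + half_width]` and never
#' exceed those bounds. A zero-sigma spec returns `center` exactly.
#'
#' @param spec A [dist_normal()] / [dist_uniform()] spec.
#' @param n Number of draws.
#' @param stream A [random_stream()].
#' @return Numeric vector of length `n`.
#' @export
draw <- function(spec, n, stream) {
  stopifnot(inherits(spec, "dist_spec"), inherits(stream, "random_stream"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be >= 1", call. = FALSE)
  with_stream(stream, switch(
    spec$kind,
    normal  = spec$center + spec$sigma * stats::rnorm(n),
    uniform = if (spec$half_width == 0) rep(spec$center, n)
              else stats::runif(n, spec$center - spec$half_width,
                                spec$center + spec$half_width),
    stop("unknown distribution kind: ", spec$kind, call. = FALSE)
  ))
}

#' Sample a water temperature with Type A and Type B components
#'
#' The measured temperature is modelled as `T0 + dT_A + dT_B`: a Type A
#' (repeated thermometer comparisons, normal) and a Type B (manufacturer
#' specification, bounded uniform) perturbation, drawn independently from
#' sub-streams `<label>/A` and `<label>/B`.
#'
#' @param T0 Thermometer reading, degrees C.
#' @param spec_a Normal Type A spec (default sigma 0.25 degC in the budgets).
#' @param spec_b Uniform Type B spec (default sigma 0.23 degC).
#' @param stream Base [random_stream()] for this source.
#' @param n Number of draws.
#' @return Temperatures in degrees C, length `n`.
#' @export
temperature_draw <- function(T0, spec_a, spec_b, stream, n = 1L) {
  stopifnot(spec_a$kind == "normal", spec_b$kind == "uniform")
  a <- draw(spec_a, n, random_stream(stream$seed, paste0(stream$label, "/A")))
  b <- draw(spec_b, n, random_stream(stream$seed, paste0(stream$label, "/B")))
  T0 + a + b
}
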