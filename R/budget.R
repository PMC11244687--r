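# Uncertainty budgets: the data model for named uncertainty sources, the
# default photon and electron budgets for a careful clinical user with
# standard instrumentation, YAML (de)serialisation, and selective zeroing.

new_source <- function(name, spec, user_controlled, group = name,
                       label = name) {
  structure(
    list(name = name, spec = spec, user_controlled = user_controlled,
         group = group, label = label),
    class = "uncertainty_source"
  )
}

new_budget <- function(modality, sources) {
  names(sources) <- vapply(sources, `[[`, "", "name")
  if (anyDuplicated(names(sources)))
    stop("duplicate source names in budget", call. = FALSE)
  structure(list(modality = modality, sources = sources),
            class = "uncertainty_budget")
}

# Canonical source names per modality, and which are under user control
# (set-up quantities: distances, depths, environmental readings, I50).
canonical_sources <- function(modality) {
  switch(modality,
    photon = c("SSD", "depth_meas", "depth_scan", "temperature_A",
               "temperature_B", "pressure", "field_size", "kQ_intrinsic",
               "kQ_formula", "repeatability", "stability", "extracameral",
               "electrometer_calibration", "chamber_calibration",
               "interim_formula", "pion_formula", "humidity"),
    electron = c("SSD", "dset", "temperature_A", "temperature_B", "pressure",
                 "I50", "R50_formula", "kecal", "kprime_formula",
                 "repeatability", "stability", "extracameral",
                 "electrometer_calibration", "chamber_calibration",
                 "pion_formula", "humidity"),
    stop("unknown modality: ", modality, call. = FALSE))
}

user_controlled_names <- function(modality) {
  switch(modality,
    photon = c("SSD", "depth_meas", "depth_scan", "temperature_A",
               "temperature_B", "pressure", "field_size"),
    electron = c("SSD", "dset", "temperature_A", "temperature_B", "pressure",
                 "I50"))
}

#' Default uncertainty budget for photon or electron calibration
#'
#' Encodes the study conditions for a careful clinical user with standard
#' instrumentation: SSD set with the ODI to within +/- 2 mm, chamber depth to
#' +/- 1 mm, MLC-defined field size to +/- 2 mm, thermometers with a 0.25 degC
#' Type A and 0.23 degC Type B uncertainty, a worst-case +/- 8 mbar digital
#' barometer, ADCL calibration factor at 0.75 % relative, electrometer at
#' 0.1 %, chamber stability 0.4 % (photon) / 0.3 % (electron), extracameral
#' current 0.1 %, repeat-irradiation scatter 0.04 %, kQ intrinsic 0.4 % and
#' fit 0.07 % (photon), interim beam-quality formula +/- 2 percentage points
#' (photon, energies above 10 MV only), I50 at sigma 0.087 cm and the R50
#' conversion formula at +/- 0.04 cm (electron), k_ecal 0.5 % and the k'R50
#' fit formula +/- 0.2 % (electron), the two-voltage recombination formula at
#' 0.2 % (normal, with the physical clamp P_ion >= 1), and humidity at
#' +/- 0.15 %.
#'
#' @param modality `"photon"` or `"electron"`.
#' @return An `uncertainty_budget`.
#' @examples
#' default_budget("photon")$sources$pressure$spec$sigma   # 4.62 mbar
#' default_budget("electron")$sources$stability$spec$sigma # 0.003
#' @export
default_budget <- function(modality = c("photon", "electron")) {
  modality <- match.arg(modality)
  shared <- list(
    new_source("SSD", dist_uniform(half_width = 0.2, unit = "cm"), TRUE,
               label = "SSD of water surface"),
    new_source("temperature_A", dist_normal(0.25, unit = "degC"), TRUE,
               group = "temperature", label = "Temperature (Type A)"),
    new_source("temperature_B", dist_uniform(sigma = 0.23, unit = "degC"),
               TRUE, group = "temperature", label = "Temperature (Type B)"),
    new_source("pressure", dist_uniform(sigma = 4.6, unit = "mbar"), TRUE,
               label = "Pressure"),
    new_source("repeatability", dist_normal(0.0004), FALSE,
               label = "Repeat irradiations of Farmer chamber"),
    new_source("extracameral", dist_normal(0.001), FALSE,
               label = "Extracameral current"),
    new_source("electrometer_calibration", dist_normal(0.001), FALSE,
               label = "Electrometer calibration"),
    new_source("chamber_calibration", dist_normal(0.0075), FALSE,
               label = "Ion chamber calibration factor"),
    new_source("pion_formula", dist_normal(0.002), FALSE,
               label = "Two voltage formula for P_ion"),
    new_source("humidity", dist_uniform(half_width = 0.0015), FALSE,
               label = "Humidity")
  )
  extra <- if (modality == "photon") list(
    new_source("depth_meas", dist_uniform(half_width = 0.1, unit = "cm"),
               TRUE, label = "Depth of Farmer chamber"),
    new_source("depth_scan", dist_uniform(half_width = 0.1, unit = "cm"),
               TRUE, label = "Scan depth for %dd(10)"),
    new_source("field_size", dist_uniform(half_width = 0.2, unit = "cm"),
               TRUE, label = "Field size"),
    new_source("kQ_intrinsic", dist_normal(0.004), FALSE,
               label = "kQ intrinsic"),
    new_source("kQ_formula", dist_normal(0.0007), FALSE,
               label = "kQ formula"),
    new_source("stability", dist_normal(0.004), FALSE,
               label = "Stability of ion chamber calibration"),
    new_source("interim_formula",
               dist_uniform(half_width = 2.0, unit = "percent_dd"), FALSE,
               label = "Interim formula for %dd(10)x")
  ) else list(
    new_source("dset", dist_uniform(half_width = 0.1, unit = "cm"), TRUE,
               label = "Depth of Farmer chamber"),
    new_source("I50", dist_uniform(sigma = 0.087, unit = "cm"), TRUE,
               label = "Depth of 50% ionization"),
    new_source("R50_formula", dist_uniform(half_width = 0.04, unit = "cm"),
               FALSE, label = "Formula for R50"),
    new_source("kecal", dist_normal(0.005), FALSE,
               label = "Beam quality k_ecal"),
    new_source("kprime_formula", dist_uniform(half_width = 0.002), FALSE,
               label = "Beam quality fitting formula k'R50"),
    new_source("stability", dist_normal(0.003), FALSE,
               label = "Stability of ion chamber calibration")
  )
  sources <- c(shared, extra)
  ord <- match(canonical_sources(modality),
               vapply(sources, `[[`, "", "name"))
  new_budget(modality, sources[ord])
}

#' @export
print.uncertainty_budget <- function(x, ...) {
  cat(sprintf("<uncertainty_budget: %s, %d sources>\n",
              x$modality, length(x$sources)))
  for (s in x$sources) {
    cat(sprintf("  %-26s %s %-9s sigma %-9.4g %-10s %s\n",
                s$name, if (s$user_controlled) "[user]" else "      ",
                s$spec$kind, s$spec$sigma, s$spec$unit,
                if (s$group != s$name) paste0("(group ", s$group, ")") else ""))
  }
  invisible(x)
}

#' Zero out selected uncertainty sources
#'
#' Returns a copy of the budget with the selected sources' sigma (and half
#' width) set to zero; the original is unchanged. With
#' `selector = "user_controlled"` every user-controlled source is zeroed
#' (photon: SSD, measurement and scan depth, temperature, pressure, field
#' size; electron: SSD, depth setting, temperature, pressure, I50) — the
#' "careful user" floor.
#'
#' @param budget An `uncertainty_budget`.
#' @param selector `"user_controlled"`, or a character vector of source names
#'   and/or group names.
#' @return A modified copy of `budget`.
#' @export
zero_sources <- function(budget, selector = "user_controlled") {
  stopifnot(inherits(budget, "uncertainty_budget"))
  if (identical(selector, "user_controlled")) {
    pick <- vapply(budget$sources, `[[`, NA, "user_controlled")
  } else {
    nm <- names(budget$sources)
    groups <- vapply(budget$sources, `[[`, "", "group")
    unknown <- setdiff(selector, c(nm, groups))
    if (length(unknown))
      stop("unknown source(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    pick <- nm %in% selector | groups %in% selector
  }
  for (i in which(pick)) {
    sp <- budget$sources[[i]]$spec
    sp$sigma <- 0
    if (sp$kind == "uniform") sp$half_width <- 0
    budget$sources[[i]]$spec <- sp
  }
  budget
}

# Replace one source's spec (used by sensitivity sweeps and overrides).
set_source_spec <- function(budget, name, spec) {
  if (is.null(budget$sources[[name]]))
    stop("unknown source: ", name, call. = FALSE)
  budget$sources[[name]]$spec <- spec
  budget
}

validate_budget <- function(budget, required) {
  missing <- setdiff(required, names(budget$sources))
  if (length(missing))
    stop("budget is missing required source(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (s in budget$sources)
    if (s$spec$sigma < 0)
      stop("negative sigma for source ", s$name, call. = FALSE)
  invisible(budget)
}

#' Read an uncertainty budget from a YAML document
#'
#' The document has top-level keys `modality`, optional logical
#' `inherit_defaults`, and `sources`, one block per source:
#' `distribution` (`normal` | `uniform`), `sigma` and/or `half_width`,
#' `unit`, optional `user_controlled`. With `inherit_defaults: true`
#' unspecified sources fall back to [default_budget()]; otherwise only the
#' listed sources exist (missing required sources surface when a chain is
#' run). Unknown source names, negative sigmas and inconsistent
#' sigma/half-width pairs are validation errors naming the offending source.
#' A schema document ships in `inst/extdata/budget-schema.md`.
#'
#' @param path Path to a YAML file (or a single YAML string).
#' @return An `uncertainty_budget`.
#' @export
load_budget <- function(path) {
  doc <- if (file.exists(path)) yaml::read_yaml(path) else yaml::yaml.load(path)
  if (is.null(doc$modality))
    stop("budget document must declare `modality`", call. = FALSE)
  modality <- match.arg(doc$modality, c("photon", "electron"))
  inherit <- isTRUE(doc$inherit_defaults)
  canon <- canonical_sources(modality)
  user_default <- user_controlled_names(modality)
  defaults <- default_budget(modality)

  listed <- doc$sources
  unknown <- setdiff(names(listed), canon)
  if (length(unknown))
    stop("unknown source name(s) in budget document: ",
         paste(unknown, collapse = ", "), call. = FALSE)

  parse_one <- function(name, blk) {
    kind <- blk$distribution
    if (is.null(kind) || !kind %in% c("normal", "uniform"))
      stop("source ", name, ": `distribution` must be normal or uniform",
           call. = FALSE)
    unit <- blk$unit %||% "relative"
    if (unit != "relative" && is.null(blk$unit))
      stop("source ", name, ": physical sources must declare a unit",
           call. = FALSE)
    uc <- blk$user_controlled %||% (name %in% user_default)
    spec <- tryCatch({
      if (kind == "normal") {
        if (is.null(blk$sigma))
          stop("normal source needs `sigma`", call. = FALSE)
        dist_normal(blk$sigma, center = blk$center %||% 0, unit = unit)
      } else {
        dist_uniform(half_width = blk$half_width, sigma = blk$sigma,
                     center = blk$center %||% 0, unit = unit)
      }
    }, error = function(e) {
      stop("source ", name, ": ", conditionMessage(e), call. = FALSE)
    })
    new_source(name, spec, uc,
               group = defaults$sources[[name]]$group %||% name,
               label = defaults$sources[[name]]$label %||% name)
  }

  parsed <- Map(parse_one, names(listed), listed)
  if (inherit) {
    sources <- defaults$sources
    for (s in parsed) sources[[s$name]] <- s
  } else {
    sources <- parsed[order(match(names(parsed), canon))]
  }
  new_budget(modality, sources)
}

#' Serialise an uncertainty budget to YAML
#'
#' Writes a complete, self-contained document (no default inheritance) that
#' [load_budget()] reads back to an equal budget.
#'
#' @param budget An `uncertainty_budget`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_budget <- function(budget, path) {
  stopifnot(inherits(budget, "uncertainty_budget"))
  blocks <- lapply(budget$sources, function(s) {
    blk <- list(distribution = s$spec$kind, sigma = s$spec$sigma,
                unit = s$spec$unit, user_controlled = s$user_controlled)
    if (s$spec$kind == "uniform") blk$half_width <- s$spec$half_width
    if (s$spec$center != 0) blk$center <- s$spec$center
    blk
  })
  yaml::write_yaml(
    list(modality = budget$modality, inherit_defaults = FALSE,
         sources = blocks),
    path, precision = 15)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
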