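# Scenario manifests are deterministic but electron ones calibrate a synthetic
# curve with an optimiser; build each once per test session.
.scenario_cache <- new.env(parent = emptyenv())

cached_scenario <- function(id) {
  if (is.null(.scenario_cache[[id]]))
    .scenario_cache[[id]] <- build_scenario(id)
  .scenario_cache[[id]]
}

# An exactly cubic curve with positive values on a window: oracle for the
# windowed-fit gradient (analytic derivative known in closed form).
cubic_curve <- function(b0 = 80, b1 = -3, b2 = 0.4, b3 = -0.05,
                        depths = seq(4, 12, by = 0.25)) {
  vals <- b0 + b1 * depths + b2 * depths^2 + b3 * depths^3
  list(curve = depth_ionization_curve(depths, vals),
       rel_grad = function(d) {
         scale <- 100 / max(vals)  # container renormalises to max 100
         v <- (b0 + b1 * d + b2 * d^2 + b3 * d^3)
         (b1 + 2 * b2 * d + 3 * b3 * d^2) / v
       })
}
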