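# Budget document schema

A budget document is YAML with three top-level keys:

```yaml
modality: photon          # or electron
inherit_defaults: true    # unlisted sources fall back to default_budget()
sources:
  <source name>:
    distribution: normal | uniform
    sigma: <number>       # standard deviation (uniform: may be derived)
    half_width: <number>  # uniform only; sigma = half_width / sqrt(3)
    unit: <text>          # "cm", "mbar", "degC", "percent_dd", "relative"
    user_controlled: true | false   # optional; defaults to the canonical
                                    # classification for the source
    center: <number>      # optional offset, default 0
```

Rules enforced by `load_budget()`:

- `modality` is required; source names must be canonical for that modality
  (see below) — anything else is an error naming the offending source.
- `sigma` and `half_width` must be non-negative; giving both requires
  `sigma == half_width / sqrt(3)` to within rounding.
- Relative (dimensionless) sources use `unit: relative`; physical sources
  must declare their unit.
- Without `inherit_defaults: true`, only the listed sources exist; a chain
  run reports any required source that is missing.

Canonical photon sources: `SSD`, `depth_meas`, `depth_scan`,
`temperature_A`, `temperature_B`, `pressure`, `field_size`, `kQ_intrinsic`,
`kQ_formula`, `repeatability`, `stability`, `extracameral`,
`electrometer_calibration`, `chamber_calibration`, `interim_formula`,
`pion_formula`, `humidity`.

Canonical electron sources: `SSD`, `dset`, `temperature_A`, `temperature_B`,
`pressure`, `I50`, `R50_formula`, `kecal`, `kprime_formula`,
`repeatability`, `stability`, `extracameral`, `electrometer_calibration`,
`chamber_calibration`, `pion_formula`, `humidity`.

User-controlled by default (set-up and environmental quantities): photon
`SSD`, `depth_meas`, `depth_scan`, `temperature_A/B`, `pressure`,
`field_size`; electron `SSD`, `dset`, `temperature_A/B`, `pressure`, `I50`.

Shipped examples: `budget_photon_6MV.yaml`, `budget_electron_6MeV.yaml`
(full dumps of the defaults). `synthetic_di_6MeV.csv` is a synthetic
depth-ionization curve in the two-column CSV format read by
`read_di_curve()` (header `depth_cm,value`).
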