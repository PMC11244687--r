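modality: electron
inherit_defaults: no
sources:
  SSD:
    distribution: uniform
    sigma: 0.115470053837925
    unit: cm
    user_controlled: yes
    half_width: 0.2
  dset:
    distribution: uniform
    sigma: 0.057735026918963
    unit: cm
    user_controlled: yes
    half_width: 0.1
  temperature_A:
    distribution: normal
    sigma: 0.25
    unit: degC
    user_controlled: yes
  temperature_B:
    distribution: uniform
    sigma: 0.23
    unit: degC
    user_controlled: yes
    half_width: 0.398371685740842
  pressure:
    distribution: uniform
    sigma: 4.6
    unit: mbar
    user_controlled: yes
    half_width: 7.967433714816835
  I50:
    distribution: uniform
    sigma: 0.087
    unit: cm
    user_controlled: yes
    half_width: 0.150688420258492
  R50_formula:
    distribution: uniform
    sigma: 0.023094010767585
    unit: cm
    user_controlled: no
    half_width: 0.04
  kecal:
    distribution: normal
    sigma: 0.005
    unit: relative
    user_controlled: no
  kprime_formula:
    distribution: uniform
    sigma: 0.001154700538379
    unit: relative
    user_controlled: no
    half_width: 0.002
  repeatability:
    distribution: normal
    sigma: 0.0004
    unit: relative
    user_controlled: no
  stability:
    distribution: normal
    sigma: 0.003
    unit: relative
    user_controlled: no
  extracameral:
    distribution: normal
    sigma: 0.001
    unit: relative
    user_controlled: no
  electrometer_calibration:
    distribution: normal
    sigma: 0.001
    unit: relative
    user_controlled: no
  chamber_calibration:
    distribution: normal
    sigma: 0.0075
    unit: relative
    user_controlled: no
  pion_formula:
    distribution: normal
    sigma: 0.002
    unit: relative
    user_controlled: no
  humidity:
    distribution: uniform
    sigma: 0.000866025403784
    unit: relative
    user_controlled: no
    half_width: 0.0015
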