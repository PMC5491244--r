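# Default parametric epithermal-beam model.
#
# Dose rates are Gy/min at the reference reactor power (1.2 MW).  The
# thermal-neutron and boron-capture components share a build-up-then-
# exponential depth shape (thermal flux moderation); their common
# penetration length (lambda_decay_cm) is calibrated so that the advantage
# depth of the weighted model equals 8.5 cm at a tumor/normal boron ratio
# of 3.5 (see calibrate_beam_model()).  The fast (recoil-proton) component
# has a short charged-particle build-up and a steep decay; the photon
# (capture-gamma) component builds up and decays slowly.  The b10
# amplitude is expressed at the reference normal-tissue boron
# concentration (25 ppm).  Absolute amplitudes are set so that a typical
# multi-field plan's total beam-on time falls in the 40-75 min range.
# The lateral profile has its half-value at the collimator edge at the
# surface, an error-function penumbra (sigma below), and an effective
# field edge that contracts with depth (in-tissue narrowing of the useful
# thermal field, down to a 3.5-cm core radius).
components:
  thermal:
    amplitude_Gy_min: 0.032
    lambda_decay_cm: 3.529349
    lambda_buildup_cm: 1.3
  fast:
    amplitude_Gy_min: 0.152
    lambda_decay_cm: 1.3
    lambda_buildup_cm: 0.45
  photon:
    amplitude_Gy_min: 0.048
    lambda_decay_cm: 16.0
    lambda_buildup_cm: 1.3
  b10:
    amplitude_Gy_min: 0.48
    lambda_decay_cm: 3.529349
    lambda_buildup_cm: 1.3
collimator_diameter_cm: 14.0
penumbra_sigma_cm: 2.0
field_contraction_cm_per_cm: 0.4
reference_boron_ppm: 25.0
reference_power_MW: 1.2
reference_flux_n_cm2_s: 1.28e9
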