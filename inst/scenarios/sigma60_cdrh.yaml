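# BSD Sigma-60 dipole ring (29 cm ring radius, ~36 cm bolus), elliptical
# CDRH phantom (35 x 25 cm muscle equivalent with 2 cm fat layer).
# Frequency / focal-point / power-ratio grid of the published benchmark;
# phases of steered drives follow from the focal point via the quadrant
# distance rule (0.1 * f * (D_i - D_max)), so they are not listed here.
# Major-axis profiles at z = 0 and z = 10 cm, each drive normalized to 100%
# at the phantom center.
name: sigma60_cdrh
device: sigma60
phantom: cdrh
bolus_length_m: 0.36
profiles:
  - {axis: major_x, z_offset_cm: 0}
  - {axis: major_x, z_offset_cm: 10}
normalization:
  kind: per_drive_center
drives:
  - name: f70_center
    f_MHz: 70
    channels:
      top: {power: 1, phase_deg: 0}
      bottom: {power: 1, phase_deg: 0}
      left: {power: 1, phase_deg: 0}
      right: {power: 1, phase_deg: 0}
  - name: f70_xm2
    f_MHz: 70
    focal_point_cm: [-2, 0]
    channels:
      top: {power: 0.72}
      bottom: {power: 0.72}
      left: {power: 1}
      right: {power: 0.47}
  - name: f80_center
    f_MHz: 80
    channels:
      top: {power: 1, phase_deg: 0}
      bottom: {power: 1, phase_deg: 0}
      left: {power: 1, phase_deg: 0}
      right: {power: 1, phase_deg: 0}
  - name: f80_xm2
    f_MHz: 80
    focal_point_cm: [-2, 0]
    channels:
      top: {power: 0.74}
      bottom: {power: 0.74}
      left: {power: 1}
      right: {power: 0.5}
  - name: f90_center
    f_MHz: 90
    channels:
      top: {power: 1, phase_deg: 0}
      bottom: {power: 1, phase_deg: 0}
      left: {power: 1, phase_deg: 0}
      right: {power: 1, phase_deg: 0}
  - name: f90_xp2
    f_MHz: 90
    focal_point_cm: [2, 0]
    channels:
      top: {power: 0.8}
      bottom: {power: 0.8}
      left: {power: 0.64}
      right: {power: 1}
  - name: f90_xp4
    f_MHz: 90
    focal_point_cm: [4, 0]
    channels:
      top: {power: 0.66}
      bottom: {power: 0.66}
      left: {power: 0.36}
      right: {power: 1}
  - name: f110_center
    f_MHz: 110
    channels:
      top: {power: 1, phase_deg: 0}
      bottom: {power: 1, phase_deg: 0}
      left: {power: 1, phase_deg: 0}
      right: {power: 1, phase_deg: 0}
  - name: f110_xm2
    f_MHz: 110
    focal_point_cm: [-2, 0]
    channels:
      top: {power: 0.78}
      bottom: {power: 0.78}
      left: {power: 1}
      right: {power: 0.58}
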