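# AMC-4, inhomogeneous 50 cm wallpaper-paste phantom (24 x 36 cm, no shell)
# with a centered 8 x 8 x 50 cm fat-equivalent tube. Absolute SAR from
# temperature-rise measurements: (1) equal amplitudes at 1000 W total with
# 45 deg on the lateral waveguides, (2) equal phases with 300 W top/bottom
# and 60 W left/right. Profiles in the midplane and at z = 10 cm.
name: amc4_fatcore
device: amc4
phantom: amc_fatcore
bolus_cm: 4
profiles:
  - {axis: major_x, z_offset_cm: 0}
  - {axis: minor_y, z_offset_cm: 0}
  - {axis: major_x, z_offset_cm: 10}
  - {axis: minor_y, z_offset_cm: 10}
normalization:
  kind: absolute
drives:
  - name: equal_1000W_lr45
    f_MHz: 70
    total_power_W: 1000
    channels:
      top: {power: 1, phase_deg: 0}
      bottom: {power: 1, phase_deg: 0}
      left: {power: 1, phase_deg: 45}
      right: {power: 1, phase_deg: 45}
  - name: tb300_lr60
    f_MHz: 70
    total_power_W: 720
    channels:
      top: {power: 300, phase_deg: 0}
      bottom: {power: 300, phase_deg: 0}
      left: {power: 60, phase_deg: 0}
      right: {power: 60, phase_deg: 0}
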