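# BSD Sigma-30 dipole ring (15 cm ring radius), cylindrical agarose phantom
# 20 cm diameter x 30 cm (sigma ~0.7 S/m, eps ~80), 130 MHz, equal
# amplitudes and phases. Radial profile along the left-right axis of the
# central midplane, normalized to 100% at the phantom center.
name: sigma30_cyl
device: sigma30
phantom: sigma30_cyl
profiles:
  - {axis: major_x, z_offset_cm: 0}
normalization:
  kind: per_drive_center
drives:
  - name: equal_130
    f_MHz: 130
    channels:
      top: {power: 1, phase_deg: 0}
      bottom: {power: 1, phase_deg: 0}
      left: {power: 1, phase_deg: 0}
      right: {power: 1, phase_deg: 0}
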