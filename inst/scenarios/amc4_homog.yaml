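# AMC-4/ALBA-4D, homogeneous elliptical saline phantom (24 x 36 cm, 2 mm PVC
# shell, sigma 0.55 S/m, eps 75 at 70 MHz), ~4 cm water boluses. Equal
# amplitudes; left/right waveguides 25 deg ahead of top/bottom. Profiles
# along both central transverse axes, normalized to 100% at the center.
name: amc4_homog
device: amc4
phantom: amc_homog
muscle: muscle_amc4
bolus_cm: 4
model_length_m: 0.60
profiles:
  - {axis: major_x, z_offset_cm: 0}
  - {axis: minor_y, z_offset_cm: 0}
normalization:
  kind: per_drive_center
drives:
  - name: tb0_lr25
    f_MHz: 70
    channels:
      top: {power: 1, phase_deg: 0}
      bottom: {power: 1, phase_deg: 0}
      left: {power: 1, phase_deg: 25}
      right: {power: 1, phase_deg: 25}
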