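# AMC-2 double waveguide, homogeneous elliptical saline phantom (24 x 36 cm,
# 2 mm PVC shell, sigma 0.51 S/m, eps 77 at 70 MHz). Equal amplitudes, top
# waveguide fixed at 0 deg, bottom phase swept. Normalized E-field profiles
# along the minor axis; the bottom-0 profile sets 100% at the phantom center.
name: amc2_homog
device: amc2
phantom: amc_homog
muscle: muscle_amc2
top_aperture_cm: 20
model_length_m: 0.60
profiles:
  - {axis: minor_y, z_offset_cm: 0}
normalization:
  kind: family_reference
  reference_drive: bottom_000
  reference_profile: minor_y_z0
drives:
  - name: bottom_m120
    f_MHz: 70
    channels: {top: {power: 1, phase_deg: 0}, bottom: {power: 1, phase_deg: -120}}
  - name: bottom_m090
    f_MHz: 70
    channels: {top: {power: 1, phase_deg: 0}, bottom: {power: 1, phase_deg: -90}}
  - name: bottom_m045
    f_MHz: 70
    channels: {top: {power: 1, phase_deg: 0}, bottom: {power: 1, phase_deg: -45}}
  - name: bottom_000
    f_MHz: 70
    channels: {top: {power: 1, phase_deg: 0}, bottom: {power: 1, phase_deg: 0}}
  - name: bottom_p045
    f_MHz: 70
    channels: {top: {power: 1, phase_deg: 0}, bottom: {power: 1, phase_deg: 45}}
  - name: bottom_p090
    f_MHz: 70
    channels: {top: {power: 1, phase_deg: 0}, bottom: {power: 1, phase_deg: 90}}
  - name: bottom_p120
    f_MHz: 70
    channels: {top: {power: 1, phase_deg: 0}, bottom: {power: 1, phase_deg: 120}}
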