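# Synthetic 5-phantom cohort of central lung tumors.
# Tumor amplitudes / GTV volumes / prescriptions and per-OAR proximity
# (d_inh) and relative organ motion (ROM) follow the published clinical
# ranges for centrally located lung SABR patients; all geometry is
# synthetic (sphere tumor, tube/ellipsoid OARs).
cohort:
  - name: phantom1
    prescription_gy: 52
    fractions: 4
    tumor: {volume_cc: 15.19, amplitude_cm: 1.74}
    breathing: {period_s: 5.0}
    oars:
      ESO: {d_inh: 3.95, rom: 0.35}
      HRT: {d_inh: -0.58, rom: 0.58}
      SC:  {d_inh: 7.5,  rom: 0.30}
      GRT: {d_inh: 1.22, rom: 1.28}
      TRA: {d_inh: 1.02, rom: 0.78}
  - name: phantom2
    prescription_gy: 50
    fractions: 5
    tumor: {volume_cc: 6.09, amplitude_cm: 0.12}
    breathing: {period_s: 2.7}
    oars:
      ESO: {d_inh: 3.75, rom: 0.35}
      HRT: {d_inh: 2.67, rom: 0.53}
      SC:  {d_inh: 7.5,  rom: 0.00}
      GRT: {d_inh: -0.29, rom: 0.29}
      TRA: {d_inh: 0.92, rom: 0.38}
  - name: phantom3
    prescription_gy: 50
    fractions: 5
    tumor: {volume_cc: 21.33, amplitude_cm: 0.25}
    breathing: {period_s: 3.6}
    oars:
      ESO: {d_inh: 1.1,  rom: 0.00}
      HRT: {d_inh: -0.3, rom: 0.10}
      SC:  {d_inh: 4.0,  rom: 0.00}
      GRT: {d_inh: 0.05, rom: 0.05}
      TRA: {d_inh: 1.85, rom: 0.05}
  - name: phantom4
    prescription_gy: 50
    fractions: 5
    tumor:
      volume_cc: 1.29
      amplitude_cm: 0.86
      direction: [0.8, 0.0, 0.6]   # lateral-dominant motion
    breathing: {period_s: 6.6}
    oars:
      ESO: {d_inh: 3.05, rom: 0.45}
      HRT: {d_inh: 1.48, rom: 0.52}
      SC:  {d_inh: 6.2,  rom: 0.00}
      GRT: {d_inh: 1.17, rom: 1.23}
      TRA: {d_inh: 0.03, rom: 0.07}
  - name: phantom5
    prescription_gy: 50
    fractions: 5
    tumor: {volume_cc: 12.01, amplitude_cm: 0.18}
    breathing: {period_s: 4.4}
    oars:
      ESO: {d_inh: 2.2,  rom: 0.30}
      HRT: {d_inh: 0.5,  rom: 0.00}
      SC:  {d_inh: 4.3,  rom: 0.00}
      GRT: {d_inh: 0.0,  rom: 0.00}
      TRA: {d_inh: -0.1, rom: 0.30}
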