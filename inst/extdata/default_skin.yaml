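# Seven-layer forearm skin model for NIR diffuse-reflectance simulation.
# Thicknesses in cm; C_B / C_H2O are blood and interstitial-water volume
# fractions; mu_s'(lambda) = musp_a * (lambda/1000 nm)^(-musp_b) in cm^-1.
# The probe window is a 0.2 mm glass plate (n = 1.4) in air.
superstrate:
  "n": 1.4
  thickness_cm: 0.02
ambient_n: 1.0
layers:
  - name: stratum_corneum
    kind: stratum_corneum
    thickness_cm: 0.002
    C_B: 0.00
    C_H2O: 0.05
    g: 0.9
    "n": 1.37
    musp_a: 30.0
    musp_b: 1.4
  - name: living_epidermis
    kind: living_epidermis
    thickness_cm: 0.008
    C_B: 0.00
    C_H2O: 0.20
    g: 0.9
    "n": 1.37
    musp_a: 28.0
    musp_b: 1.4
  - name: papillary_dermis
    kind: dermal
    thickness_cm: 0.02
    C_B: 0.04
    C_H2O: 0.50
    g: 0.9
    "n": 1.37
    musp_a: 22.0
    musp_b: 1.3
  - name: upper_blood_net_dermis
    kind: dermal
    thickness_cm: 0.01
    C_B: 0.30
    C_H2O: 0.60
    g: 0.9
    "n": 1.37
    musp_a: 24.0
    musp_b: 1.3
  - name: reticular_dermis
    kind: dermal
    thickness_cm: 0.16
    C_B: 0.04
    C_H2O: 0.70
    g: 0.9
    "n": 1.37
    musp_a: 20.0
    musp_b: 1.3
  - name: deep_blood_net_dermis
    kind: dermal
    thickness_cm: 0.012
    C_B: 0.10
    C_H2O: 0.70
    g: 0.9
    "n": 1.37
    musp_a: 20.0
    musp_b: 1.3
  - name: subcutaneous_tissue
    kind: subcutaneous
    thickness_cm: 0.65
    C_B: 0.05
    C_H2O: 0.70
    g: 0.9
    "n": 1.37
    musp_a: 15.0
    musp_b: 0.8
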