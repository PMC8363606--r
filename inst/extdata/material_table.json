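{
  "version": "1.0",
  "comment": "Constitutive coefficients for computational stenting: reduced-polynomial soft materials (MPa), stent alloys, balloon compliance moduli.",
  "soft": {
    "silicone":    {"C": [0.154]},
    "normal_wall": {"C": [6.52e-3, 4.89e-2, 9.26e-3, 0.76, -0.43, 8.69e-2]},
    "very_soft":   {"C": [0.045, 0.17, -0.13, 0.11], "yield": 0.12},
    "soft":        {"C": [0.01, 0.49, 4.13], "yield": 0.71},
    "neutral":     {"C": [0.06, 4.28, -21.36, 69.36], "yield": 1.37},
    "stiff":       {"C": [0.11, 9.06], "yield": 1.81},
    "very_stiff":  {"C": [0.21, 64.86, -3.5e3, 1.999e5], "yield": 627}
  },
  "plaque_classes": ["very_soft", "soft", "neutral", "stiff", "very_stiff"],
  "alloys": {
    "MP35N": {"E_GPa": 233, "yield_MPa": 414, "tensile_MPa": 930,
              "elongation_pct": 45, "density_g_cm3": 8.40,
              "hardening": "isotropic"},
    "PtIr":  {"E_GPa": 224, "yield_MPa": 285, "density_g_cm3": 21.6,
              "hardening": "perfect"},
    "PtCr":  {"E_GPa": 203, "yield_MPa": 480, "tensile_MPa": 834,
              "elongation_pct": 45, "density_g_cm3": 9.90,
              "hardening": "isotropic"}
  },
  "balloon_moduli_MPa": {"compliant": 300, "semi_compliant": 900,
                         "non_compliant": 1500},
  "silicone_density_g_cm3": 2.32
}
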