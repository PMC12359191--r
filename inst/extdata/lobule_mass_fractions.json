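{
  "comment": "Masses (g) and mass fractions of the nine tissue components of the microscale hexagonal liver lobule model. Fractions are percent; masses are per single lobule.",
  "percent": true,
  "total_mass_g": 8.22e-05,
  "components": {
    "central_vein":   {"mass_g": 1.23e-06, "fraction": 1.50},
    "portal_arteries":{"mass_g": 5.04e-08, "fraction": 0.06},
    "portal_veins":   {"mass_g": 4.50e-07, "fraction": 0.55},
    "bile_ducts":     {"mass_g": 7.12e-08, "fraction": 0.09},
    "bile_canaliculi":{"mass_g": 4.36e-06, "fraction": 5.30},
    "sinusoids":      {"mass_g": 1.26e-05, "fraction": 15.38},
    "space_of_disse": {"mass_g": 2.77e-06, "fraction": 3.37},
    "kupffer_cells":  {"mass_g": 1.05e-07, "fraction": 0.13},
    "hepatocytes":    {"mass_g": 6.05e-05, "fraction": 73.63}
  }
}
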