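[
  {"eye_id": "demo_sphere12",   "rho_mm": 12.0,   "bump_A_mm": 0.0,  "seed": 11},
  {"eye_id": "demo_reference",  "rho_mm": 8.4375, "bump_A_mm": 0.0,  "seed": 12},
  {"eye_id": "demo_staphyloma", "rho_mm": 12.0,   "bump_A_mm": 0.35, "bump_sigma_mm": 1.2, "seed": 13}
]
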