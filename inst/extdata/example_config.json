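{
  "_comment": "Example site configuration for qc_config(file = ...). Any top-level key overrides the shipped default; intervals are [lower, upper] pairs in the documented units (weight kg, dose Bq).",
  "allowed_tracers": ["FDG", "FLUTEMETAMOL"],
  "expected_pet_scanner": "SIEMENS Biograph64 VG51C",
  "expected_mr_scanner": "Philips Ingenia CX",
  "subject_id_pattern": "^[A-Z]+[0-9]{5}$",
  "weight_interval": [40, 150],
  "dose_interval": [1.5e8, 3.5e8],
  "t1_designation": "T1"
}
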