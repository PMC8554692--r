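{
  "classic_proband_age": 45,
  "classic_relative_age": 45,
  "chompret_proband_age": 46,
  "chompret_relative_age": 56,
  "chompret_breast_age": 31,
  "premenopausal_fallback_age": 50,
  "require_rms_subtype": false
}
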