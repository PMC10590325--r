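# Example configuration override: entries here replace the repo defaults
# from default_config(); omitted entries keep their defaults. Use this as
# a template for dropping in an externally estimated parameter set.
population_parameters:
  ke_ara: 4.5        # 1/day, effective elimination of the active exposure
  v_ara: 37.3        # L
  beta1: 0.25        # G-CSF exponent on proliferation
  beta2: 0.125       # G-CSF exponent on transit/release
infusions_per_day: 1  # set 2 for q12h administration
provenance: repo-default
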