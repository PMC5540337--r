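# Default model constants for Anopheles gambiae; any subset of these
# fields may be overridden in a user config passed via --params or
# read_species_params().
species: Anopheles gambiae
appearances_per_mosquito_hour:
  FA1: 72.3
  FA2_LOW: 9.5
  FA2_HIGH: 1.5
  FA3: 0.3
encounter_coefficient: 9.0e-06
passage_roof:
  slope: 0.34
  intercept: -0.55
passage_side:
  slope: 0.30
  intercept: -0.52
impassable_width: 5
section_length: 10
max_entry_dimension: 300
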