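study:
  name: potato-fixture-demo
  seed: 1
  discount_rate: 0.10
  pathways: [static, SSP1-RCP4.5, SSP2-RCP6.0, SSP3-RCP8.5]
  technologies: potato_fixtures
  technology_seed: 1
world:
  generator:
    n_regions: 12
    target_share: 0.5
    focus_value_share: 0.15
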