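# Example run configuration for seqcua.
# Base-case analysis of the bundled regimens plus the four tornado scenarios.
strategies: [PD, PGD, PDG, PDE, PGDE, PDEG]
comparisons:
  - [PGD, PD]
  - [PDG, PD]
  - [PGDE, PDE]
  - [PDEG, PDE]
half_cycle: false
surgery: stay
cohort:
  start_age: 40
  life_expectancy: 73.6
  cycle_length: 0.5
economy:
  gdp_per_capita_usd: 3756
  exchange_rate: 23486
discount_rate: 0.03
sensitivity:
  fraction: 0.20
output_dir: seqcua-out
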