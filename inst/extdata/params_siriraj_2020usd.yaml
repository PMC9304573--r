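# Base-case model inputs for the Thai kidney-transplantation cost-utility
# model (2020 USD). One block per parameter; `family` is the PSA sampling
# distribution, `role` controls clamping of deterministic-sensitivity bounds.
settings:
  discount_rate: 0.03
  wtp: 5113
  start_age: 50
  kt_stop_age: 65
  max_age: 100
  discount_bounds: [0.0, 0.06]
parameters:
  - {name: p_dialysis_to_kt_lrkt, value: 0.36, se: 0.084, family: beta,
     units: per year, role: probability}
  - {name: p_dialysis_to_kt_ddkt, value: 0.18, se: 0.041, family: beta,
     units: per year, role: probability}
  - {name: p_graft_loss_year1, value: 0.04, se: 0.004, family: beta,
     units: per year, role: probability}
  - {name: p_graft_loss_subsequent, value: 0.01, se: 0.001, family: beta,
     units: per year, role: probability}
  # Standardized mortality ratios of ESKD patients vs the general
  # population, by age band; held fixed in the PSA.
  - {name: smr_50_59, value: 8.6, se: 0.3061, family: fixed, role: ratio}
  - {name: smr_60_69, value: 4.6, se: 0.2041, family: fixed, role: ratio}
  - {name: smr_70_79, value: 1.9, se: 0.1531, family: fixed, role: ratio}
  - {name: smr_80plus, value: 7.8, se: 0.1531, family: fixed, role: ratio}
  # Pooled mortality ratio of dialysis-ESKD vs transplanted patients.
  - {name: mortality_ratio_eskd_kt, value: 2.19, se: 0.352, family: fixed,
     role: ratio}
  # Costs shared across strategies
  - {name: cost_dialysis, value: 13734, se: 2060, family: gamma,
     units: USD/yr, role: cost}
  - {name: cost_nonmedical, value: 1059, se: 257, family: gamma,
     units: USD/yr, role: cost}
  # Alternative literature-based dialysis costing profile
  - {name: cost_dialysis_literature, value: 12193, se: 4236, family: gamma,
     units: USD/yr, role: cost}
  - {name: cost_dialysis_complication, value: 481, se: 481, family: gamma,
     units: USD/mo, role: cost}
  # Preemptive LRKT
  - {name: cost_kt_plrkt, value: 7816, se: 507, family: gamma,
     units: USD/visit, role: cost}
  - {name: cost_post1_plrkt, value: 17592, se: 1139, family: gamma,
     units: USD/yr, role: cost}
  - {name: cost_subsequent_plrkt, value: 9886, se: 584, family: gamma,
     units: USD/yr, role: cost}
  - {name: cost_waiting_plrkt, value: 6879, se: 917, family: gamma,
     units: USD, role: cost}
  # Non-preemptive LRKT
  - {name: cost_kt_nplrkt, value: 9104, se: 1070, family: gamma,
     units: USD/visit, role: cost}
  - {name: cost_post1_nplrkt, value: 15453, se: 1067, family: gamma,
     units: USD/yr, role: cost}
  - {name: cost_subsequent_nplrkt, value: 11709, se: 825, family: gamma,
     units: USD/yr, role: cost}
  # Non-preemptive DDKT
  - {name: cost_kt_npddkt, value: 13908, se: 1545, family: gamma,
     units: USD/visit, role: cost}
  - {name: cost_post1_npddkt, value: 19520, se: 1361, family: gamma,
     units: USD/yr, role: cost}
  - {name: cost_subsequent_npddkt, value: 10478, se: 440, family: gamma,
     units: USD/yr, role: cost}
  # Health-state utilities
  - {name: utility_dialysis, value: 0.68, se: 0.1, family: beta,
     role: utility}
  - {name: utility_kt, value: 0.781, se: 0.117, family: beta, role: utility}
  - {name: utility_post1, value: 0.889, se: 0.133, family: beta,
     role: utility}
  - {name: utility_subsequent, value: 0.889, se: 0.133, family: beta,
     role: utility}
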