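{
  "as1_barrier_with_rad21": 14.1,
  "as1_barrier_without_rad21": 28.1,
  "as2_barrier_activated": 14.2,
  "as2_barrier_reduction": 38.0,
  "separation_dg": 24.8,
  "two_atp_hydrolysis_dg": 30.6,
  "units": "kcal/mol"
}
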