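{
  "stage": "simulate",
  "t_end": 1000,
  "name": "mapk-balanced-g1_1-gch_1",
  "mode": "constant_substrate",
  "v_S": 0,
  "S_fixed": 90,
  "S0": 90,
  "seed": 1,
  "a1": 0.0135,
  "d1": 0.675,
  "k1": 1.5,
  "a2": 0.0135,
  "d2": 0.675,
  "k2": 1.5,
  "a_ch": 0.0135,
  "d_ch": 0.675,
  "k_ch": 1,
  "k1_ch": 1.5,
  "k2_ch": 1.5,
  "k_deg": 0,
  "kbar1": 0,
  "two_site": false,
  "a_ch2": 0.0135,
  "d_ch2": 0.675,
  "k_ch2_turn": 1.5,
  "E1_tot": 50,
  "E2_tot": 50,
  "E12_tot": 50
}
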