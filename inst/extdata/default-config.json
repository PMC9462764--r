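{
  "domain": {
    "Lx": 10,
    "Ly": 10
  },
  "mechanics": {
    "k_rep": 150,
    "gamma": 7,
    "alpha_0": 89.2901203516887,
    "F_max": 10,
    "k_phi": 100,
    "eta": 10,
    "dt": 0.00833333333333333,
    "R_0": 0.5,
    "neighbour_cutoff": 2,
    "division_offset": 0.3,
    "growth_time": 1
  },
  "desquamation": {
    "dx": 1,
    "F_D": 5,
    "contact_gap": 0.7
  },
  "prolif": {
    "cycle_low": 13,
    "cycle_high": 17,
    "population_mode": "single",
    "T_1": 10,
    "dT_C": 20,
    "fraction_fast": 0.5
  },
  "coupling": {
    "h_corneum_base": 4,
    "f_h": 1,
    "burn_in_days": 30,
    "sample_days": 30,
    "realisations": 10,
    "fill_days": 12,
    "fill_ceiling": 12
  },
  "chem": {
    "s_0": 1e-05,
    "e_T": 1e-10
  },
  "rates": {
    "k_plus1": 149100000,
    "k_minus1": 0,
    "k_2": 6870,
    "K_M": 4.6e-05,
    "a3": 15.6,
    "b3": 58.5,
    "A3": 6900000,
    "B3": 3
  },
  "ph": {
    "c0": 6.8482,
    "c1": -0.3765,
    "c2": -5.1663,
    "c3": 3.1792
  },
  "scenario": {
    "inhibitor_fraction": 1
  },
  "seed": 1
}
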