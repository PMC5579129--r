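{
  "name": "whiting",
  "notes": "Mobile midwater whiting-like exemplar: larger, more mobile schools with more fish each (larger F_s and F_n, smaller tau_l than groundfish); all other parameters shared with the groundfish scenario.",
  "provenance": "synthetic calibration: absolute values are package calibration constants, not a real stock's ecology. They were chosen once so that (a) the lone-searcher mean search time is a few hundred timesteps, (b) a season completes in 1e3-1e4 steps, (c) the whiting/groundfish sign structure (F_s, F_n, tau_l) holds with all other parameters shared, and (d) the groundfish case sits in the regime where information sharing substantially raises unsuccessful-group CPUE while the successful group loses mildly relative to low sharing. turn_rate is the encounter-optimal rate returned by optimize_turn_rate() for this world.",
  "world": {
    "L": 40,
    "n_schools": 5,
    "F_s": 4.0,
    "F_n": 300,
    "tau_l": 25,
    "dt": 0.1
  },
  "agents": {
    "v": 1.0,
    "r_sense": 2.0,
    "C_q": 1.0,
    "turn_rate": 0.0018
  },
  "n_agents": 20,
  "T": 1600,
  "t_max": 3000
}
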