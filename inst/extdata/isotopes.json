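{
  "comment": "Positron emitters produced by protons of at most 7.5 MeV in O-18 enriched tissue. Integrated cross sections are the value of the integral of sigma(E) dE from 0 to Ep at Ep = 7.5 MeV, in mb*MeV.",
  "Ep_MeV": 7.5,
  "isotopes": {
    "C11": {
      "name": "C11",
      "half_life_min": 20.364,
      "reaction_channel": "14N(p,X)11C",
      "threshold_MeV": 3.13,
      "integrated_xs_mb_MeV": 75.1,
      "target_element": "N"
    },
    "N13": {
      "name": "N13",
      "half_life_min": 9.965,
      "reaction_channel": "16O(p,X)13N",
      "threshold_MeV": 5.55,
      "integrated_xs_mb_MeV": 53.3,
      "target_element": "O"
    },
    "F18": {
      "name": "F18",
      "half_life_min": 109.77,
      "reaction_channel": "18O(p,n)18F",
      "threshold_MeV": 2.57,
      "integrated_xs_mb_MeV": 1130.71,
      "target_element": "O"
    }
  },
  "excluded": {
    "O15": {"reason": "production cut-off energy 16.79 MeV exceeds the beam energy"},
    "C11_from_C12": {"reason": "threshold 17.9 MeV for 12C(p,X)11C exceeds the beam energy"}
  }
}
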