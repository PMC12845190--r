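{
  "lipinski": {"mw_max": 500, "logp_max": 4.15, "hbd_max": 5, "hba_max": 10},
  "ghose": {"mw_min": 160, "mw_max": 480, "logp_min": -0.4, "logp_max": 5.6,
            "mr_min": 40, "mr_max": 130, "atoms_min": 20, "atoms_max": 70},
  "veber": {"rotb_max": 10, "tpsa_max": 140},
  "egan": {"logp_max": 5.88, "tpsa_max": 131.6},
  "muegge": {"mw_min": 200, "mw_max": 600, "logp_min": -2, "logp_max": 5,
             "tpsa_max": 150, "rings_max": 7, "carbons_min_exclusive": 4,
             "heteroatoms_min_exclusive": 1, "rotb_max": 15,
             "hba_max": 10, "hbd_max": 5},
  "cns_logp": {"min": 2.0, "max": 3.5}
}
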