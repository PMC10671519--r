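{
  "Ba": {
    "cation": "Ba",
    "anion": "Cl",
    "nu": 2,
    "anion_oxygens": 0,
    "default_hydration": 0
  },
  "Sr": {
    "cation": "Sr",
    "anion": "Cl",
    "nu": 2,
    "anion_oxygens": 0,
    "default_hydration": 0
  },
  "Ca": {
    "cation": "Ca",
    "anion": "Cl",
    "nu": 2,
    "anion_oxygens": 0,
    "default_hydration": 0
  },
  "Mn": {
    "cation": "Mn",
    "anion": "Cl",
    "nu": 2,
    "anion_oxygens": 0,
    "default_hydration": 0
  },
  "Zn": {
    "cation": "Zn",
    "anion": "SO4",
    "nu": 1,
    "anion_oxygens": 4,
    "default_hydration": 0
  },
  "Cu": {
    "cation": "Cu",
    "anion": "SO4",
    "nu": 1,
    "anion_oxygens": 4,
    "default_hydration": 8
  },
  "Ni": {
    "cation": "Ni",
    "anion": "SO4",
    "nu": 1,
    "anion_oxygens": 4,
    "default_hydration": 4
  }
}
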