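{
  "community": {
    "members": [
      {
        "genus": "Bacillus",
        "strain": "Bacillus velezensis",
        "proportion": 0.2
      },
      {
        "genus": "Escherichia",
        "strain": "Escherichia coli",
        "proportion": 0.2
      },
      {
        "genus": "Lactococcus",
        "strain": "Lactococcus lactis",
        "proportion": 0.2
      },
      {
        "genus": "Pseudomonas",
        "strain": "Pseudomonas proteolytica",
        "proportion": 0.2
      },
      {
        "genus": "Staphylococcus",
        "strain": "Staphylococcus haemolyticus",
        "proportion": 0.2
      }
    ],
    "spike_density": 10000000
  },
  "methods": {
    "shotgun": {
      "w_live": 1,
      "w_dead": 1,
      "uses_activity": false,
      "suppresses_dead_dna": false
    },
    "pma_shotgun": {
      "w_live": 1,
      "w_dead": 0.05,
      "uses_activity": false,
      "suppresses_dead_dna": true
    },
    "metat": {
      "w_live": 1,
      "w_dead": 0.01,
      "uses_activity": true,
      "suppresses_dead_dna": false
    },
    "s16": {
      "w_live": 1,
      "w_dead": 0.1,
      "uses_activity": true,
      "suppresses_dead_dna": false
    }
  },
  "platforms": {
    "illumina": {
      "depth": 1000000,
      "misclass_rate": 0.002
    },
    "ont": {
      "depth": 100000,
      "misclass_rate": 0.02
    }
  },
  "n_replicates": 3,
  "background": {
    "Acinetobacter": 1000,
    "Corynebacterium": 1000,
    "Streptococcus": 1000
  },
  "growth_mean": 10,
  "sigma_growth": 0.5,
  "activity": {
    "Pseudomonas": 5
  },
  "activity_default": 1,
  "sigma_q": 0.1,
  "seed": 1
}
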