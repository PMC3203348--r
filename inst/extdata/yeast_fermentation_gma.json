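{
  "schema": "kinetic-model/1",
  "name": "yeast anaerobic fermentation (GMA)",
  "metabolites": [
    {
      "id": "glci",
      "basal": 0.0345,
      "co_metabolite": false
    },
    {
      "id": "g6p",
      "basal": 1.011,
      "co_metabolite": false
    },
    {
      "id": "fdp",
      "basal": 9.144,
      "co_metabolite": false
    },
    {
      "id": "pep",
      "basal": 0.0095,
      "co_metabolite": false
    },
    {
      "id": "atp",
      "basal": 1.1278,
      "co_metabolite": false
    }
  ],
  "enzymes": [
    {
      "id": "HXT",
      "basal": 19.7,
      "display_name": "HXT"
    },
    {
      "id": "GLK",
      "basal": 68.5,
      "display_name": "GLK"
    },
    {
      "id": "PFK",
      "basal": 31.7,
      "display_name": "PFK"
    },
    {
      "id": "TDH",
      "basal": 49.9,
      "display_name": "TDH"
    },
    {
      "id": "PYK",
      "basal": 3440,
      "display_name": "PYK"
    },
    {
      "id": "TPS",
      "basal": 14.31,
      "display_name": "TPS"
    },
    {
      "id": "GOL",
      "basal": 203,
      "display_name": "GOL"
    },
    {
      "id": "ATPase",
      "basal": 25.1,
      "display_name": "ATPase"
    }
  ],
  "stoichiometry": {
    "metabolites": ["glci", "g6p", "fdp", "pep", "atp"],
    "rates": ["HXT", "GLK", "PFK", "TDH", "PYK", "TPS", "GOL", "ATPase"],
    "matrix": [
      [1, -1, 0, 0, 0, 0, 0, 0],
      [0, 1, -1, 0, 0, -1, 0, 0],
      [0, 0, 1, -1, 0, 0, -1, 0],
      [0, 0, 0, 2, -1, 0, 0, 0],
      [0, -1, -1, 2, 1, -1, 0, -1]
    ]
  },
  "rates": [
    {
      "id": "HXT",
      "enzyme": "HXT",
      "kind": "power_law",
      "expression": "k * g6p ^ -0.2344 * HXT",
      "parameters": {
        "k": 0.811123742624192
      }
    },
    {
      "id": "GLK",
      "enzyme": "GLK",
      "kind": "power_law",
      "expression": "k * glci ^ 0.74639999999999995 * atp ^ 0.024299999999999999 * GLK",
      "parameters": {
        "k": 2.8632
      }
    },
    {
      "id": "PFK",
      "enzyme": "PFK",
      "kind": "power_law",
      "expression": "k * g6p ^ 0.73180000000000001 * atp ^ -0.39410000000000001 * PFK",
      "parameters": {
        "k": 0.522519384208573
      }
    },
    {
      "id": "TDH",
      "enzyme": "TDH",
      "kind": "power_law",
      "expression": "k * fdp ^ 0.6159 * atp ^ 0.1308 * TDH",
      "parameters": {
        "k": 0.0758497180519342
      }
    },
    {
      "id": "PYK",
      "enzyme": "PYK",
      "kind": "power_law",
      "expression": "k * fdp ^ 0.050000000000000003 * pep ^ 0.53300000000000003 * atp ^ -0.082199999999999995 * PYK",
      "parameters": {
        "k": 0.0945
      }
    },
    {
      "id": "TPS",
      "enzyme": "TPS",
      "kind": "power_law",
      "expression": "k * g6p ^ 8.6106999999999996 * TPS",
      "parameters": {
        "k": 0.0009
      }
    },
    {
      "id": "GOL",
      "enzyme": "GOL",
      "kind": "power_law",
      "expression": "k * fdp ^ 0.5 * GOL",
      "parameters": {
        "k": 0.00146260690156322
      }
    },
    {
      "id": "ATPase",
      "enzyme": "ATPase",
      "kind": "power_law",
      "expression": "k * atp ^ 1 * ATPase",
      "parameters": {
        "k": 0.997200197172501
      }
    }
  ],
  "basal_fluxes": {
    "HXT": 15.9382145686594,
    "GLK": 15.9382145686594,
    "PFK": 15.924063380073,
    "TDH": 15.0262382337086,
    "PYK": 30.0524764674172,
    "TPS": 0.0141511885863749,
    "GOL": 0.897825146364358,
    "ATPase": 28.2285237975158
  }
}
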