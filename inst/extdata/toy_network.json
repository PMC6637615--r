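{
  "meta": {
    "schema_version": "1.0"
  },
  "entities": [
    {
      "id": "M0",
      "kind": "metabolite",
      "name": "M0"
    },
    {
      "id": "M1",
      "kind": "metabolite",
      "name": "M1"
    },
    {
      "id": "M2",
      "kind": "metabolite",
      "name": "M2"
    },
    {
      "id": "M3",
      "kind": "metabolite",
      "name": "M3"
    },
    {
      "id": "M4",
      "kind": "metabolite",
      "name": "M4"
    },
    {
      "id": "M5",
      "kind": "metabolite",
      "name": "M5"
    },
    {
      "id": "M6",
      "kind": "metabolite",
      "name": "M6"
    },
    {
      "id": "E1",
      "kind": "gene",
      "name": "E1"
    },
    {
      "id": "E1_p",
      "kind": "protein",
      "name": "E1_p",
      "gene": "E1"
    },
    {
      "id": "E2",
      "kind": "gene",
      "name": "E2"
    },
    {
      "id": "E2_p",
      "kind": "protein",
      "name": "E2_p",
      "gene": "E2"
    },
    {
      "id": "E3",
      "kind": "gene",
      "name": "E3"
    },
    {
      "id": "E3_p",
      "kind": "protein",
      "name": "E3_p",
      "gene": "E3"
    },
    {
      "id": "E4",
      "kind": "gene",
      "name": "E4"
    },
    {
      "id": "E4_p",
      "kind": "protein",
      "name": "E4_p",
      "gene": "E4"
    },
    {
      "id": "E5",
      "kind": "gene",
      "name": "E5"
    },
    {
      "id": "E5_p",
      "kind": "protein",
      "name": "E5_p",
      "gene": "E5"
    },
    {
      "id": "TF0",
      "kind": "gene",
      "name": "TF0"
    },
    {
      "id": "TF0_p",
      "kind": "protein",
      "name": "TF0_p",
      "gene": "TF0"
    },
    {
      "id": "TF1",
      "kind": "gene",
      "name": "TF1"
    },
    {
      "id": "TF1_p",
      "kind": "protein",
      "name": "TF1_p",
      "gene": "TF1"
    },
    {
      "id": "TF2",
      "kind": "gene",
      "name": "TF2"
    },
    {
      "id": "TF2_p",
      "kind": "protein",
      "name": "TF2_p",
      "gene": "TF2"
    }
  ],
  "reactions": [
    {
      "id": "R1",
      "direction": "left-to-right",
      "reactants": [
        "M0"
      ],
      "products": [
        "M1"
      ],
      "enzymes": [
        "E1_p"
      ]
    },
    {
      "id": "R2",
      "direction": "left-to-right",
      "reactants": [
        "M1"
      ],
      "products": [
        "M2"
      ],
      "enzymes": [
        "E2_p"
      ]
    },
    {
      "id": "R3",
      "direction": "left-to-right",
      "reactants": [
        "M2"
      ],
      "products": [
        "M3"
      ],
      "enzymes": [
        "E3_p"
      ]
    },
    {
      "id": "R4",
      "direction": "left-to-right",
      "reactants": [
        "M3"
      ],
      "products": [
        "M6"
      ],
      "enzymes": [
        "E4_p"
      ]
    },
    {
      "id": "R5",
      "direction": "left-to-right",
      "reactants": [
        "M4"
      ],
      "products": [
        "M5"
      ],
      "enzymes": [
        "E5_p"
      ]
    }
  ],
  "regulations": [
    {
      "id": "G1",
      "regulator": "TF0_p",
      "regulatee": "TF1",
      "mode": "transcriptional",
      "sign": "-"
    },
    {
      "id": "G2",
      "regulator": "TF0_p",
      "regulatee": "E5",
      "mode": "transcriptional",
      "sign": "+"
    },
    {
      "id": "G3",
      "regulator": "TF1_p",
      "regulatee": "E1",
      "mode": "transcriptional",
      "sign": "+"
    },
    {
      "id": "G4",
      "regulator": "TF2_p",
      "regulatee": "E2",
      "mode": "transcriptional",
      "sign": "+"
    },
    {
      "id": "G5",
      "regulator": "TF0_p",
      "regulatee": "TF2",
      "mode": "transcriptional",
      "sign": "+"
    }
  ],
  "transcription_units": [
    {
      "id": "TU1",
      "genes": [
        "E2",
        "E3"
      ]
    }
  ]
}
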