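{
  "name": "emt_core_fixture",
  "n_species": 21,
  "n_interactions": 38,
  "species_by_kind": {
    "protein": 15,
    "gene": 0,
    "rna": 3,
    "complex": 2,
    "phenotype": 1,
    "degradation": 0,
    "unknown": 0
  },
  "interactions_by_category": {
    "state_transition": 34,
    "complex_association": 0,
    "dissociation": 0,
    "transport": 0,
    "unknown_transition": 0,
    "logical_activation": 4
  },
  "input_nodes": [
    "TGFB"
  ],
  "epithelial_markers": ["ECadherin", "ZO1", "miR200", "GRHL2", "OVOL2"],
  "mesenchymal_markers": ["SNAIL", "ZEB", "TWIST", "Goosecoid", "NCadherin"],
  "phenotype_node": "EMT",
  "edges": [
    {
      "source": "TGFB",
      "sign": "activation",
      "target": "TGFBR",
      "note": "TGFbeta ligand binding assembles and activates the TGFbetaRII/RI receptor complex"
    },
    {
      "source": "TGFBR",
      "sign": "activation",
      "target": "SMAD",
      "note": "the active receptor complex phosphorylates R-SMADs, which trimerise with SMAD4 and translocate to the nucleus"
    },
    {
      "source": "SMAD",
      "sign": "activation",
      "target": "SNAIL",
      "note": "TGFbeta/SMAD signalling drives transcription of SNAIL family factors"
    },
    {
      "source": "NFKB",
      "sign": "activation",
      "target": "SNAIL",
      "note": "NF-kB signalling amplifies SNAIL activity"
    },
    {
      "source": "GSK3B",
      "sign": "inhibition",
      "target": "SNAIL",
      "note": "GSK-3beta targets SNAIL for degradation, suppressing EMT"
    },
    {
      "source": "miR34",
      "sign": "inhibition",
      "target": "SNAIL",
      "note": "miR-34 and SNAIL form a mutually inhibitory feedback loop"
    },
    {
      "source": "SNAIL",
      "sign": "inhibition",
      "target": "miR34",
      "note": "SNAIL represses miR-34 in the mutually inhibitory loop"
    },
    {
      "source": "ZEB",
      "sign": "inhibition",
      "target": "miR34",
      "note": "ZEB contributes to downregulation of the epithelial miRNAs"
    },
    {
      "source": "SNAIL",
      "sign": "inhibition",
      "target": "miR200",
      "note": "SNAIL contributes to downregulation of the miR-200 family"
    },
    {
      "source": "ZEB",
      "sign": "inhibition",
      "target": "miR200",
      "note": "ZEB and miR-200 form a mutually inhibitory feedback loop"
    },
    {
      "source": "miR200",
      "sign": "inhibition",
      "target": "ZEB",
      "note": "miR-200 represses ZEB in the mutually inhibitory loop"
    },
    {
      "source": "SNAIL",
      "sign": "activation",
      "target": "ZEB",
      "note": "ZEB expression is primarily driven by SNAIL"
    },
    {
      "source": "GRHL2",
      "sign": "inhibition",
      "target": "ZEB",
      "note": "GRHL2 and ZEB form a mutually inhibitory loop stabilising hybrid states"
    },
    {
      "source": "ZEB",
      "sign": "inhibition",
      "target": "GRHL2",
      "note": "ZEB represses GRHL2 in the mutually inhibitory loop"
    },
    {
      "source": "OVOL2",
      "sign": "inhibition",
      "target": "ZEB",
      "note": "OVOL2 and ZEB form a mutually inhibitory loop"
    },
    {
      "source": "ZEB",
      "sign": "inhibition",
      "target": "OVOL2",
      "note": "ZEB represses OVOL2 in the mutually inhibitory loop"
    },
    {
      "source": "SNAIL",
      "sign": "inhibition",
      "target": "GRHL2",
      "note": "EMT transcription factors repress epithelial phenotype-stability genes"
    },
    {
      "source": "SNAIL",
      "sign": "inhibition",
      "target": "OVOL2",
      "note": "EMT transcription factors repress epithelial phenotype-stability genes"
    },
    {
      "source": "SNAIL",
      "sign": "inhibition",
      "target": "ECadherin",
      "note": "SNAIL represses E-cadherin through its E-boxes"
    },
    {
      "source": "SNAIL",
      "sign": "inhibition",
      "target": "ZO1",
      "note": "TGFbeta-driven SNAIL suppresses the tight-junction protein ZO-1"
    },
    {
      "source": "TGFBR",
      "sign": "activation",
      "target": "AKT",
      "note": "the receptor complex activates PI3K/AKT independently of SMADs"
    },
    {
      "source": "TWIST",
      "sign": "activation",
      "target": "AKT",
      "note": "TWIST and AKT form a double-positive feedback loop"
    },
    {
      "source": "AKT",
      "sign": "activation",
      "target": "TWIST",
      "note": "AKT induces TWIST in the double-positive feedback loop"
    },
    {
      "source": "AKT",
      "sign": "inhibition",
      "target": "GSK3B",
      "note": "AKT stabilises SNAIL by blocking GSK-3beta"
    },
    {
      "source": "AKT",
      "sign": "activation",
      "target": "NFKB",
      "note": "AKT signalling activates NF-kB"
    },
    {
      "source": "NFKB",
      "sign": "activation",
      "target": "NKILA",
      "note": "NF-kB induces the lncRNA NKILA"
    },
    {
      "source": "NKILA",
      "sign": "inhibition",
      "target": "NFKB",
      "note": "NKILA feeds back negatively on NF-kB, yielding oscillations"
    },
    {
      "source": "SNAIL",
      "sign": "activation",
      "target": "Goosecoid",
      "note": "SNAIL drives the mesenchymal marker Goosecoid"
    },
    {
      "source": "SNAIL",
      "sign": "activation",
      "target": "NCadherin",
      "note": "EMT transcription factors promote mesenchymal phenotype-associated genes"
    },
    {
      "source": "ZEB",
      "sign": "activation",
      "target": "NCadherin",
      "note": "EMT transcription factors promote mesenchymal phenotype-associated genes"
    },
    {
      "source": "p53",
      "sign": "activation",
      "target": "miR200",
      "note": "p53 sustains epithelial miRNAs that preserve E-cadherin expression"
    },
    {
      "source": "p53",
      "sign": "activation",
      "target": "miR34",
      "note": "p53 sustains epithelial miRNAs that preserve E-cadherin expression"
    },
    {
      "source": "MDM2",
      "sign": "inhibition",
      "target": "p53",
      "note": "MDM2 targets p53 for degradation"
    },
    {
      "source": "SMAD",
      "sign": "activation",
      "target": "MDM2",
      "note": "abstraction: TGFbeta/SMAD signalling is taken to induce MDM2, relieving p53 control of the epithelial miRNAs"
    },
    {
      "source": "SNAIL",
      "sign": "activation",
      "target": "EMT",
      "note": "EMT onset requires the core mesenchymal regulators"
    },
    {
      "source": "ZEB",
      "sign": "activation",
      "target": "EMT",
      "note": "EMT onset requires the core mesenchymal regulators"
    },
    {
      "source": "TWIST",
      "sign": "activation",
      "target": "EMT",
      "note": "EMT onset requires the core mesenchymal regulators"
    },
    {
      "source": "ECadherin",
      "sign": "inhibition",
      "target": "EMT",
      "note": "intact E-cadherin junctions oppose the EMT phenotype"
    }
  ]
}
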