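{
    "compartments": {
        "c": "",
        "e": ""
    },
    "genes": [],
    "id": "toy_overflow",
    "metabolites": [
        {
            "compartment": "e",
            "formula": "C6H12O6",
            "id": "glc_e",
            "name": "glucose"
        },
        {
            "compartment": "e",
            "formula": "O2",
            "id": "o2_e",
            "name": "oxygen"
        },
        {
            "compartment": "c",
            "formula": "C2H4O",
            "id": "prec_c",
            "name": "biomass precursor"
        },
        {
            "compartment": "e",
            "formula": "C2H3O2",
            "id": "ac_e",
            "name": "acetate"
        },
        {
            "compartment": "e",
            "formula": "CO2",
            "id": "co2_e",
            "name": "carbon dioxide"
        }
    ],
    "reactions": [
        {
            "gene_reaction_rule": "",
            "id": "RESP",
            "lower_bound": 0,
            "metabolites": {
                "glc_e": -1,
                "o2_e": -1,
                "prec_c": 3
            },
            "name": "",
            "upper_bound": 1000
        },
        {
            "gene_reaction_rule": "",
            "id": "OVER",
            "lower_bound": 0,
            "metabolites": {
                "ac_e": 1,
                "co2_e": 2,
                "glc_e": -1,
                "prec_c": 1
            },
            "name": "",
            "upper_bound": 1000
        },
        {
            "gene_reaction_rule": "",
            "id": "ACRESP",
            "lower_bound": 0,
            "metabolites": {
                "ac_e": -1,
                "o2_e": -1,
                "prec_c": 1
            },
            "name": "",
            "upper_bound": 1000
        },
        {
            "gene_reaction_rule": "",
            "id": "BIOMASS_toy",
            "lower_bound": 0,
            "metabolites": {
                "prec_c": -30
            },
            "name": "",
            "objective_coefficient": 1.0,
            "upper_bound": 1000
        },
        {
            "gene_reaction_rule": "",
            "id": "EX_glc_e",
            "lower_bound": -10,
            "metabolites": {
                "glc_e": -1
            },
            "name": "",
            "upper_bound": 1000
        },
        {
            "gene_reaction_rule": "",
            "id": "EX_ac_e",
            "lower_bound": -10,
            "metabolites": {
                "ac_e": -1
            },
            "name": "",
            "upper_bound": 1000
        },
        {
            "gene_reaction_rule": "",
            "id": "EX_o2_e",
            "lower_bound": -20,
            "metabolites": {
                "o2_e": -1
            },
            "name": "",
            "upper_bound": 1000
        },
        {
            "gene_reaction_rule": "",
            "id": "EX_co2_e",
            "lower_bound": -1000,
            "metabolites": {
                "co2_e": -1
            },
            "name": "",
            "upper_bound": 1000
        }
    ],
    "version": "1"
}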