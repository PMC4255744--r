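# Example laboratory configuration: equipment list, biochemical-entity
# dictionary with external IDs, abbreviation table and default settings.
# Labs are expected to copy and adapt this file; the pipeline treats it as
# the lab-specific half of the knowledge base (the action catalog being
# the lab-independent half).
equipment:
  - name: "Thermo Scientific Forma Direct Heat CO2 Incubator TC 230"
    aliases: ["CO2 incubator"]
    id_source: "lab-internal"
    id_value: "EQ-001"
  - name: "Incu-Shaker Mini"
    aliases: ["shaking incubator"]
    id_source: "lab-internal"
    id_value: "EQ-002"
  - name: "10 ml glass pipette"
    aliases: ["glass pipette"]
    id_source: "lab-internal"
    id_value: "EQ-003"
  - name: "conical centrifuge tube"
    aliases: ["conical tube"]
    id_source: "lab-internal"
    id_value: "EQ-004"
  - name: "water bath"
    aliases: []
    id_source: "lab-internal"
    id_value: "EQ-005"
entities:
  - name: "Trichloroacetic acid"
    aliases: []
    id_source: "NCBI Pubchem"
    id_value: "6421"
  - name: "Dimethylsulfoxide"
    aliases: []
    id_source: "NCBI Pubchem"
    id_value: "679"
  - name: "Bovine Serum Albumin"
    aliases: []
    id_source: "UniProt"
    id_value: "P02769"
  - name: "bFGF"
    aliases: ["basic fibroblast growth factor"]
    id_source: "UniProt"
    id_value: "P09038"
  - name: "EGF"
    aliases: ["epidermal growth factor"]
    id_source: "UniProt"
    id_value: "P01133"
  - name: "yeast growth culture"
    aliases: []
    id_source: "lab-internal"
    id_value: "ENT-001"
  - name: "phosphate-buffered saline"
    aliases: []
    id_source: "NCBI Pubchem"
    id_value: "24978514"
  - name: "distilled water"
    aliases: ["dH2O"]
    id_source: "NCBI Pubchem"
    id_value: "962"
  - name: "ethanol"
    aliases: []
    id_source: "NCBI Pubchem"
    id_value: "702"
  - name: "LB medium"
    aliases: ["LB broth"]
    id_source: "lab-internal"
    id_value: "ENT-002"
  - name: "lysis buffer"
    aliases: []
    id_source: "lab-internal"
    id_value: "ENT-003"
  - name: "agarose gel"
    aliases: []
    id_source: "lab-internal"
    id_value: "ENT-004"
abbreviations:
  TCA: "Trichloroacetic acid"
  "ON": "overnight"   # quoted: bare ON is a YAML 1.1 boolean
  RT: "room temperature"
  DMSO: "Dimethylsulfoxide"
  PBS: "phosphate-buffered saline"
  BSA: "Bovine Serum Albumin"
  EtOH: "ethanol"
defaults:
  overnight: "16 h"
  room temperature: "22 °C"
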