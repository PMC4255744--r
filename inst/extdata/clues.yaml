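# Semantic-clue table: lexical triggers that signal a descriptor value in
# protocol text. The unit inventory is versioned here so it can be extended
# as new protocols are processed. `word: true` marks units written as words
# (matched with an optional plural "s" and a word boundary); symbol units
# are matched literally. Unit IDs refer to the Units Ontology (UO); units
# with no canonical UO accession carry an empty id.
version: "1.0"
units:
  - {symbol: "μg/mL", kind: concentration, unit_id: "UO:0000274", word: false}
  - {symbol: "mg/mL",      kind: concentration, unit_id: "UO:0000176", word: false}
  - {symbol: "°C",    kind: temperature,   unit_id: "UO:0000027", word: false}
  - {symbol: "°F",    kind: temperature,   unit_id: "UO:0000195", word: false}
  - {symbol: "K",          kind: temperature,   unit_id: "UO:0000012", word: false}
  - {symbol: "hour",       kind: period,        unit_id: "UO:0000032", word: true}
  - {symbol: "hr",         kind: period,        unit_id: "UO:0000032", word: true}
  - {symbol: "h",          kind: period,        unit_id: "UO:0000032", word: true}
  - {symbol: "minute",     kind: period,        unit_id: "UO:0000031", word: true}
  - {symbol: "min",        kind: period,        unit_id: "UO:0000031", word: true}
  - {symbol: "second",     kind: period,        unit_id: "UO:0000010", word: true}
  - {symbol: "sec",        kind: period,        unit_id: "UO:0000010", word: true}
  - {symbol: "s",          kind: period,        unit_id: "UO:0000010", word: true}
  - {symbol: "day",        kind: period,        unit_id: "UO:0000033", word: true}
  - {symbol: "week",       kind: period,        unit_id: "UO:0000034", word: true}
  - {symbol: "μL",    kind: volume,        unit_id: "UO:0000101", word: false}
  - {symbol: "mL",         kind: volume,        unit_id: "UO:0000098", word: false}
  - {symbol: "L",          kind: volume,        unit_id: "UO:0000099", word: false}
  - {symbol: "rpm",        kind: speed,         unit_id: "",           word: true}
  - {symbol: "×g",    kind: speed,         unit_id: "",           word: false}
  - {symbol: "%",          kind: concentration, unit_id: "UO:0000187", word: false}
  - {symbol: "mM",         kind: concentration, unit_id: "UO:0000063", word: false}
  - {symbol: "μM",    kind: concentration, unit_id: "UO:0000064", word: false}
  - {symbol: "M",          kind: concentration, unit_id: "UO:0000062", word: false}
goal_cues:
  - "in order to"
condition_cues:
  - "under"
  - "in the presence of"
  - "with <gerund>"
protocol_method_cues:
  - "according to"
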