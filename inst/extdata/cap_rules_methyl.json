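{
  "comment": "Example of a richer capping table offering a methyl group as an alternative to a single hydrogen for open valence 1. The optimiser prefers the hydrogen (fewer heavy atoms); the methyl option exercises the selection machinery and can be promoted by editing the table.",
  "rules": [
    {"element": "*", "open": 1,
     "options": [
       [{"element": "H", "attach": 0, "order": 1}],
       [{"element": "C", "attach": 0, "order": 1},
        {"element": "H", "attach": 1, "order": 1},
        {"element": "H", "attach": 1, "order": 1},
        {"element": "H", "attach": 1, "order": 1}]
     ]}
  ]
}
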