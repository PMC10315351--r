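{
  "comment": "Default capping table: hydrogen-only, neutral and apolar. An atom with open valence v receives v single-bonded hydrogens. The built-in fallback rule implements the same behavior; this file documents the config format.",
  "rules": [
    {"element": "*", "open": 1,
     "options": [[{"element": "H", "attach": 0, "order": 1}]]},
    {"element": "*", "open": 2,
     "options": [[{"element": "H", "attach": 0, "order": 1},
                  {"element": "H", "attach": 0, "order": 1}]]},
    {"element": "*", "open": 3,
     "options": [[{"element": "H", "attach": 0, "order": 1},
                  {"element": "H", "attach": 0, "order": 1},
                  {"element": "H", "attach": 0, "order": 1}]]}
  ]
}
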