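{
  "comment": "Default stylized 16-sensor insole layout (4 x 4 grid, mm; x medial-lateral, y posterior-to-anterior). Identical to default_insole_layout().",
  "left": [[18, 48], [6, 48], [-6, 48], [-18, 48], [18, 96], [6, 96], [-6, 96], [-18, 96], [18, 144], [6, 144], [-6, 144], [-18, 144], [18, 192], [6, 192], [-6, 192], [-18, 192]],
  "right": [[-18, 48], [-6, 48], [6, 48], [18, 48], [-18, 96], [-6, 96], [6, 96], [18, 96], [-18, 144], [-6, 144], [6, 144], [18, 144], [-18, 192], [-6, 192], [6, 192], [18, 192]]
}
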