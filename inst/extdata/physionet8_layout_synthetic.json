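{
  "comment": "SYNTHETIC stand-in layout for 8-sensor-per-foot VGRF records: a stylized 2-column x 4-row grid in mm (x medial-lateral, y posterior-to-anterior). The true device coordinates are not shipped with the public records; supply your own layout for spatially calibrated COP values.",
  "left": [[-15, 30], [15, 30], [-15, 100], [15, 100], [-15, 170], [15, 170], [-15, 230], [15, 230]],
  "right": [[-15, 30], [15, 30], [-15, 100], [15, 100], [-15, 170], [15, 170], [-15, 230], [15, 230]]
}
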