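# Example phantom configuration: the package's default head-and-neck layout.
# Positions and radii in mm on a 128 x 128 mm single-slice grid.
grid_shape: [64, 64, 1]
spacing: [2.0, 2.0, 2.0]
placement: fixed
prescriptions:
  CTV1: 70.0
  CTV2: 59.85
  CTV3: 53.90
structures:
  name:   [CTV1, CTV2, CTV3, BRS, SC, MAN, LAR, PHY, PARL, PARR, COCHL, COCHR, SMGL, SMGR, ESO]
  role:   [CTV1, CTV2, CTV3, OAR, OAR, OAR, OAR, OAR, OAR, OAR, OAR, OAR, OAR, OAR, OAR]
  x:      [64, 60, 86, 64, 64, 64, 64, 64, 30, 98, 26, 102, 42, 86, 64]
  y:      [64, 68, 52, 22, 10, 44, 94, 80, 60, 60, 30, 30, 88, 92, 110]
  z:      [0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0]
  radius: [14, 20, 9, 8, 4, 7, 7, 6, 8, 8, 3, 3, 6, 6, 5]
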