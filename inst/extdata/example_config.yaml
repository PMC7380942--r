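# Example run configuration.  Omitted keys take package defaults.
seed: 1
profile:
  diaHigh: 1        # dimensionless DIA total at the leading edge
  diaLow: 0.4       # ... at the rear
  rockHigh: 2       # dimensionless ROCK total on the rear/body segment
  rockLow: 1        # ... on the front segment
  xSwitch: 0.9      # rear/body fraction of the cell length
  cellLength: 50    # um
diffusion:
  dRhoActive: 0.2   # um^2/s, membrane-bound active forms
  dRhoInactive: 20  # um^2/s, cytosolic GDI-bound forms
  dRacActive: 0.2
  dRacInactive: 20
solver:
  tMax: 1200        # s
  dt: 1             # splitting step, s
  outputDt: 5       # frame interval, s
  nNodes: 200
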