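# Dual-probe tracking geometry: PILATUS-100K-style detector, pink beam.
detector:
  pitch_mm: 0.172
  rows: 195
  cols: 487
  center: [97.0, 243.0]
  distance_mm: 95.0
  frame_interval_s: 0.0125
  masks:
    - [0, 4, 0, 486]      # intermodule strip (row0, row1, col0, col1)
beam:
  energy_keV: 17.7
  bandwidth: 0.1
  mode: pink
phases:
  - name: Au
    system: cubic
    a: 4.08
  - name: ZnO
    system: hexagonal
    a: 3.25
    c: 5.2
rings:
  - phase: Au
    hkl: [1, 1, 1]
    half_width_px: 2
  - phase: ZnO
    hkl: [1, 0, 0]
    half_width_px: 2
  - phase: ZnO
    hkl: [0, 0, 2]
    half_width_px: 2
  - phase: ZnO
    hkl: [1, 0, 1]
    half_width_px: 2
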