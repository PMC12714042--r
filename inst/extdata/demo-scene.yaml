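# Compact demonstration scene: a three-state refractive-index staircase
# on an 8 x 8-tile mosaic. Sections override default_run_config().
scene:
  geometry:
    n_tiles_x: 8
    n_tiles_y: 8
    tile_px: 4
  protocol:
    levels: [1.333, 1.341, 1.3495]
    state_duration_s: 200
  frame_period_s: 20
spectrometer:
  period_s: 40
  step_nm: 0.5
  noise_sigma: 0.001
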