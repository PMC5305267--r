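# Example configuration: a graded-stimulus polarization run at low tension.
params:
  "N": 64
  mt0: 0.2
solver:
  t_end: 150
  snapshot_every: 1
stimulus:
  kind: graded
  ks_amp: 0.004
  ks_dur: 20
  direction: 0
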