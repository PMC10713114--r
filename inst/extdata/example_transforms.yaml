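# Example per-channel transformation config.
CD3:
  kind: logicle
  params: {t: 262144, w: 0.5, m: 4.5, a: 0}
CD4:
  kind: logicle
  params: {t: 262144, w: 0.5, m: 4.5, a: 0}
CD25:
  kind: arcsinh
  params: {a: 0, b: 0.2, c: 0}
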