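# Example gating tree: a lymphocyte-style rectangle, a Treg-style
# polygon inside it, and a quadrant split of the Tregs.
- id: lymph
  shape: rectangle
  channels: [CD3, CD4]
  geometry: {xmin: 2.0, xmax: 4.5, ymin: 2.0, ymax: 4.5}
- id: tregs
  shape: polygon
  channels: [CD25, FoxP3]
  parent: lymph
  geometry:
    vertices:
      - [2.0, 2.0]
      - [4.5, 2.0]
      - [4.5, 4.5]
      - [2.0, 4.5]
- id: ctla4_split
  shape: quadrant
  channels: [CTLA4, CD127]
  parent: tregs
  geometry: {cx: 2.0, cy: 2.0}
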