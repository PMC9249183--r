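# Anchor parameter set of the published parameter studies
geometry:
  segments:
    - {kind: stenosis, height: 0.1, length: 0.2, gap: 0.2}
    - {kind: dilatation, height: 0.1, length: 0.2, gap: 0.6}
  domain_length: auto
casson:
  plug_radius: 0.2
forces:
  M: 2.0
  F: 0.3
  phi: pi/6
flux: 0.1
mode: paper
quadrature_points: 2001
radial_probe: 0.2
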