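# Reconstructed merge topology of the width-tuned two-stage gradient
# generator. Weights are feed-channel widths in um (flow taken
# proportional to width at equal channel length and height); the interior
# routing is a reconstruction consistent with the stated feed widths and
# the designed 1 : 1/2 : 1/4 : 0 output ladder, not a printed schematic.
inlets:
  dye: 1.0
  buffer: 0.0
stages:
  B:
    - weight: 150.0
      source: dye
    - weight: 150.0
      source: buffer
  C:
    - weight: 50.0
      source: dye
    - weight: 150.0
      source: buffer
outputs:
  - dye
  - B
  - C
  - buffer
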