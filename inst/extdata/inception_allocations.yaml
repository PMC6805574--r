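# Per-branch channel allocations of the seven Inception modules at full
# width.  Modules 3a-4d use the canonical GoogLeNet allocations, whose
# branch totals equal the published per-module output widths.  The
# published 4e total (1856) exceeds the canonical 4e total (832), so its
# four output branches are scaled proportionally (largest-remainder
# rounding) and the two reducers by the same ratio; the scaled values are
# recorded here for reference.  network_architecture() recomputes them.
modules:
  3a: {b1: 64,  b3r: 96,  b3: 128, b5r: 16, b5: 32,  pp: 32,  total: 256}
  3b: {b1: 128, b3r: 128, b3: 192, b5r: 32, b5: 96,  pp: 64,  total: 480}
  4a: {b1: 192, b3r: 96,  b3: 208, b5r: 16, b5: 48,  pp: 64,  total: 512}
  4b: {b1: 160, b3r: 112, b3: 224, b5r: 24, b5: 64,  pp: 64,  total: 512}
  4c: {b1: 128, b3r: 128, b3: 256, b5r: 24, b5: 64,  pp: 64,  total: 512}
  4d: {b1: 112, b3r: 144, b3: 288, b5r: 32, b5: 64,  pp: 64,  total: 528}
  4e: {b1: 571, b3r: 357, b3: 714, b5r: 71, b5: 286, pp: 285, total: 1856}
residual_links:
  - {src: 4c, dst: 4e, point: input}
  - {src: 4d, dst: 4e, point: output}
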