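# Default (old) Braun-Blanquet cover-abundance scale; midpoints in percent.
name: braun_blanquet_old
codes:
  r: 0.1
  "+": 0.5
  "1": 2.5
  "2": 15
  "3": 37.5
  "4": 62.5
  "5": 87.5
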