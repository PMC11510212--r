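# Synthetic 5-HT2A-style segment table: author-number ranges are
# approximate (constructed for examples/tests), but the anchors reproduce
# the standard Ballesteros-Weinstein assignments R173 = 3.50, E318 = 6.30,
# V333 = 6.45, W336 = 6.48 (note 6.48@336 implies the other TM6 pairs).
segments:
  TM3:  {start: 156, end: 183, anchor: "3.50@173"}
  ECL2: {start: 219, end: 230, anchor: "45.52@227"}
  TM5:  {start: 234, end: 265}
  TM6:  {start: 313, end: 343, anchor: "6.48@336"}
  TM7:  {start: 363, end: 386}
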