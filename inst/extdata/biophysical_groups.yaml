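# Default seven-group biophysical classification of the 20 standard amino acids.
# A partition: every residue belongs to exactly one group. Configurable data.
groups:
  aliphatic: AVLI
  aromatic: FWY
  polar_neutral: STNQ
  acidic: DE
  basic: KRH
  sulfur: CM
  conformational: GP
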