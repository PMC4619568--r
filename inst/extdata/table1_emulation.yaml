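# Default three-library study design emulated by the synthetic repertoire
# generator: per-library pre-selection chain counts, canonical-combination
# mixtures, CDR-H3 length distributions and post-selection clone panels.
# Mixture/length values are weights; the generator normalizes them to
# probabilities. Minor categories absent from the weights receive no mass.
linker: EGKSSGASGESKVDD
mutation_rates:
  fw: 0.01
  cdr: 0.15
post_copies: 2
planted_conserved:
  mode: identical
  heavy: ["5", "10", "12", "19", "22", "36", "38", "45", "48", "66", "70",
          "72", "76", "80", "82", "82A", "86", "90", "92", "103", "105", "108"]
  lambda: ["3", "7", "11", "15", "19", "23", "35", "40", "45", "47", "57",
           "61", "67", "73", "75", "82", "86", "98", "100", "104"]
libraries:
  - id: library1
    n_pre_heavy: 110
    n_pre_lambda: 80
    heavy_mixture: {"1-1": 97.3, "2-4": 1.0, "1-4": 1.0}
    lambda_mixture: {"6-1-X": 51.3, "2-1-5": 11.2, "6-1-5": 11.2, "2-1-X": 10.0}
    h3_lengths: {"14": 14.5, "13": 11.8, "12": 10.0, "11": 8.18}
    l3_x_lengths: {"10": 62.5, "12": 10.0, "13": 14.0}
    post_panels:
      - {target: SQA, n_clones: 6}
      - {target: POR, n_clones: 3}
  - id: library2
    n_pre_heavy: 77
    n_pre_lambda: 30
    heavy_mixture: {"1-1": 94.8, "2-1": 2.6, "3-1": 1.3}
    lambda_mixture: {"6-1-X": 46.7, "6-1-5": 20.0, "5-1-X": 16.6, "5-1-4": 2.0}
    h3_lengths: {"11": 18.0, "14": 16.0, "13": 12.0, "12": 10.0}
    l3_x_lengths: {"10": 56.7, "12": 13.3}
    post_panels:
      - {target: COP, n_clones: 8}
  - id: library3
    n_pre_heavy: 196
    n_pre_lambda: 95
    heavy_mixture: {"1-1": 100.0}
    lambda_mixture: {"6-1-X": 45.3, "5-1-X": 14.7, "2-1-X": 17.7, "5-1-5": 5.26}
    h3_lengths: {"13": 16.0, "14": 15.0, "15": 13.0, "12": 10.0}
    l3_x_lengths: {"10": 67.4, "12": 7.4}
    post_panels:
      - {target: HSL, n_clones: 6}
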