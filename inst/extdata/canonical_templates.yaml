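# Built-in canonical structure templates (strict Chothia SDR style).
# Curated data, configurable: loop windows are Chothia-style loop spans given in
# Kabat codes, 'length' is the residue count over that window, and 'keys' list
# the structurally determining residues with their allowed amino acids.
# A loop length matching no template of that loop is labelled "X"; a
# length-compatible template whose key residues are violated yields "unmatched".
templates:
  - chain: heavy
    loop: H1
    class: "1"
    window: ["26", "35"]
    length: 10
    keys:
      - {code: "26", allowed: "G"}
      - {code: "27", allowed: "FYGSD"}
      - {code: "34", allowed: "MILVWT"}
  - chain: heavy
    loop: H1
    class: "2"
    window: ["26", "35"]
    length: 11
    keys:
      - {code: "26", allowed: "G"}
      - {code: "27", allowed: "FYGSD"}
      - {code: "34", allowed: "MILVWT"}
  - chain: heavy
    loop: H1
    class: "3"
    window: ["26", "35"]
    length: 12
    keys:
      - {code: "26", allowed: "G"}
      - {code: "27", allowed: "FYGSD"}
      - {code: "34", allowed: "MILVWT"}
  - chain: heavy
    loop: H2
    class: "1"
    window: ["50", "58"]
    length: 9
    keys:
      - {code: "55", allowed: "GSDN"}
      - {code: "71", allowed: "ASTRKVL"}
  - chain: heavy
    loop: H2
    class: "2"
    window: ["50", "58"]
    length: 10
    keys:
      - {code: "55", allowed: "GSDN"}
      - {code: "71", allowed: "ASTRKVL"}
  - chain: heavy
    loop: H2
    class: "3"
    window: ["50", "58"]
    length: 11
    keys:
      - {code: "55", allowed: "GSDN"}
      - {code: "71", allowed: "ASTRKVL"}
  - chain: heavy
    loop: H2
    class: "4"
    window: ["50", "58"]
    length: 12
    keys:
      - {code: "55", allowed: "GSDN"}
      - {code: "71", allowed: "ASTRKVL"}
  - chain: lambda
    loop: L1
    class: "2"
    window: ["24", "34"]
    length: 11
    keys:
      - {code: "25", allowed: "GSATN"}
      - {code: "33", allowed: "GASNT"}
  - chain: lambda
    loop: L1
    class: "3"
    window: ["24", "34"]
    length: 12
    keys:
      - {code: "25", allowed: "GSATN"}
      - {code: "33", allowed: "GASNT"}
  - chain: lambda
    loop: L1
    class: "5"
    window: ["24", "34"]
    length: 13
    keys:
      - {code: "25", allowed: "GSATN"}
      - {code: "33", allowed: "GASNT"}
  - chain: lambda
    loop: L1
    class: "6"
    window: ["24", "34"]
    length: 14
    keys:
      - {code: "25", allowed: "GSATN"}
      - {code: "33", allowed: "GASNT"}
  - chain: lambda
    loop: L2
    class: "1"
    window: ["50", "56"]
    length: 7
    keys:
      - {code: "55", allowed: "P"}
  - chain: lambda
    loop: L3
    class: "4"
    window: ["89", "97"]
    length: 9
    keys:
      - {code: "90", allowed: "SAQTN"}
      - {code: "95", allowed: "STAGLVP"}
  - chain: lambda
    loop: L3
    class: "5"
    window: ["89", "97"]
    length: 11
    keys:
      - {code: "90", allowed: "SAQTN"}
      - {code: "95", allowed: "STAGLVP"}
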