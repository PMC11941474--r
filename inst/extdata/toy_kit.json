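{
  "repeat1": "GTTGGGCCGTCGGGGGAACTAG",
  "repeat2": "GCGCGCCCTGGGGCTGTTAACC",
  "upstream_anneal": "GCCGTGCCCCGCCAATCGTG",
  "downstream_anneal": "CGCTCGGGGCCAGCACAACT",
  "backbone": "AACTGGTCGGGGACGAACGGACAACGGAGTTTGGCTCCAGGGCAGAAGAGCCGTCTGCCGGATGTCCTGCCCCGCGCGGCGCCGTGCCCCGCCAATCGTGGCCGAATTCGAATTGCGTTGGGCCGTCGGGGGAACTAGGATGTCTGCCGTTTCACCGCTGGTCCCGAGGCGCGCCCTGGGGCTGTTAACCTTATCCCTCCCCGCTTAGTGCGAGCCGGCCGTGCGAGCGACTCCCCCCCCATCAGGCGCCGGCCGACCCATATGCGCTCGGGGCCAGCACAACTGCACCGGGGCCACCGCCCATCGCCTGCCGGCCAAGCCCCAGCCACGAAGGCCGACTTTAC",
  "enzymes": {
    "NdeI": "CATATG",
    "HindIII": "AAGCTT",
    "BstBI": "TTCGAA",
    "NcoI": "CCATGG",
    "SnaBI": "TACGTA"
  },
  "destination_enzymes": ["BstBI", "NdeI"],
  "min_overlap": 20,
  "spacer_len": 34
}
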