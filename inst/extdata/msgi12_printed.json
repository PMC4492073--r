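{
  "description": "Published summary tables and headline counts of the MSGI 1.2 alfalfa expression atlas, transcribed for arithmetic verification.",
  "table1": {
    "species": ["P.vulgaris", "G.max", "M.truncatula", "M.sativa"],
    "primary_transcripts": [27197, 56044, 50894, 112626],
    "with_arabidopsis_hit": [25119, 49304, 35644, 64631],
    "unique_arabidopsis": [14283, 15407, 15170, 15607]
  },
  "table2": {
    "classes": ["B47", "F56", "shared"],
    "total_snps": [38645, 44800, 26796],
    "tissue_specific_snps": [23879, 25875, 4083],
    "transcripts_with_snps": [10861, 11585, 6749]
  },
  "table3": {
    "tissues": ["Leaf", "Flower", "ES", "PES", "Root", "Nodule"],
    "de_transcripts": [5596, 6892, 5636, 1723, 2094, 4112]
  },
  "table6": {
    "tissues": ["Leaf", "Flower", "ES", "PES", "Root", "Nodule"],
    "expressed": {
      "B47": [71003, 78163, 77220, 73768, 77840, 75442],
      "F56": [74251, 79320, 74612, 76693, 76167, 72594]
    },
    "tissue_specific": {
      "B47": [1712, 3970, 581, 293, 3374, 7491],
      "F56": [1233, 4199, 475, 332, 2821, 7605]
    },
    "common": [255, 2919, 70, 52, 1329, 5736],
    "totals": {
      "expressed": { "B47": 104787, "F56": 104040 },
      "tissue_specific": { "B47": 17421, "F56": 16665 },
      "common": 10361
    },
    "all_total": 112626
  },
  "headline": {
    "n_transcripts": 112626,
    "de_between_subspecies_total": 26053,
    "de_within_B47_total": 58932,
    "de_within_F56_total": 69143,
    "snp_total": 110241,
    "transcripts_with_snps": 17317,
    "b47_specific_transcripts": 7826,
    "b47_specific_single_tissue": 2944,
    "f56_specific_transcripts": 8573,
    "f56_specific_single_tissue": 2253,
    "tissue_specific_union": 23725,
    "nodule_specific_union": 9360,
    "annotated_transcripts": 90388,
    "pct_de_between_printed": 23,
    "pct_b47_specific_single_tissue_printed": 37,
    "pct_f56_specific_single_tissue_printed": 26,
    "pct_nodule_of_tissue_specific_printed": 40
  }
}
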