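{
  "source_id": "synthetic tRNA-Phe(GAA) template (cloverleaf layout, no accession)",
  "anticodon_triplet": "GAA",
  "coordinates": "0-based half-open on the gene sequence",
  "domains": {
    "ACC5": [0, 7],
    "DDOM": [7, 26],
    "ANTICODON": [26, 43],
    "TDOM": [43, 66],
    "ACC3": [66, 73]
  }
}
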