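{
  "description": "Literature + TCGA tally of high-PolyPhen CIC missense mutations by protein domain",
  "missense_total": 77,
  "by_domain": {
    "HMG_box": 60,
    "GlobDom": 15,
    "outside": 2
  }
}
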