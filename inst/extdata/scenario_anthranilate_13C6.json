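{
  "precursor_name": "[13C6]anthranilate",
  "labels": [
    {
      "element": "C",
      "isotope": "13C",
      "n_labeled": 6,
      "n_retained": 6
    }
  ],
  "note": "Ring-carbon-labelled anthranilate is loaded directly by the first adenylation domain; the whole anthraniloyl unit, including all six labelled ring carbons, is retained in the product, predicting a nominal m/z shift of +6 Da."
}
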