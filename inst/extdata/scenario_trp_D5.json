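{
  "precursor_name": "L-tryptophan-D5 (indole ring)",
  "labels": [
    {
      "element": "H",
      "isotope": "2H",
      "n_labeled": 5,
      "n_retained": 4
    }
  ],
  "note": "Indoleamine 2,3-dioxygenase cleaves the indole 2,3-bond of tryptophan to give N-formyl-kynurenine; the ring C2 position becomes the N-formyl carbon, which is removed (with its deuterium) by deformylation to kynurenine before incorporation. Four of the five ring deuteria survive, predicting a nominal m/z shift of +4 Da rather than +5."
}
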