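{
  "seed": 1,
  "lenA": 30,
  "lenB": 20,
  "n_seqs": 500,
  "n_pairs": 400,
  "n_decoys": 30,
  "coupling_strength": 1.0,
  "max_id": 0.9,
  "max_gap_frac": 0.5,
  "id_threshold": 0.8,
  "mode": "adjacent_downstream",
  "max_gap": 500,
  "min_sep": 6,
  "cutoff": 8,
  "threshold": 0.5,
  "form": "sigmoid",
  "include_cluster": true,
  "include_corrinoid": true
}
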