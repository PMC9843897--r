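# Small demonstration world (runs in a few seconds).
seed: 101
tissue: liver
outdir: convexpr_demo
simulate:
  n_species: 4
  n_genes: 400
  samples_per_species: 3
  n_convergent_up: 10
  n_convergent_down: 10
  library_size_range: [200000, 500000]
  methylation:
    n_promoters: 40
    n_differential: 10
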