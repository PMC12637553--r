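# Small end-to-end pipeline configuration on synthetic data.
out_dir: spanmf_run
seed: 7
simulate:
  n_cells_per_region: 300
  regions: [thalamus, germinal zones, cortical plate]
  n_factors_true: 3
  n_genes: 40
  n_batches: 2
qc:
  max_transcripts: 1000
fit:
  n_factors_init: 6
  epochs: 1200
  learning_rate: 0.01
summarize:
  enrichment_threshold: 0.33
enrich_regions: {}
de_regions:
  per_region_cap: 25000
dnm_burden:
  n_probands: 20000
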