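# Demo pipeline configuration. Every stage block is optional; omitted
# fields fall back to the package defaults, which are echoed into the run
# manifest.
seed: 20260929
simulate:
  n_snps: 4000
  n_enhancers: 600
  n_genes: 150
  tag_depth: 100000
  n_background_peaks: 300
integrate:
  alpha: 0.05
  window: 500
  tf_label: "TF"
motif:
  window: 500
  bin_bp: 25
  core_bp: 150
gsea:
  n_perm: 500
tagmatrix:
  k: 2
superenhancer:
  stitch_bp: 12500
kinetics:
  r_min: 0.5
  k: 4
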