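# End-to-end demonstration run: a simulated two-subpopulation panel with a
# hard selective sweep (s = 0.05, ~95 generations old) in the second
# subpopulation. The sweep region reaches genome-wide significance in the
# DRC_150 locus table of pop2.
# Usage:
#   cfg <- pipeline_config(file = system.file("extdata", "demo_config.yaml",
#                                             package = "sweepscan"))
#   run_pipeline(cfg, "demo_out")
seed: 6
sim:
  n_founders: 2000
  pop_size: 600
  n_generations_burnin: 40
  split_generation: 120
  chrom_length_cM: 40
  n_variants: 6000
  sweep:
    focal_variant_index: 3000
    selection_coefficient: 0.05
    sweep_start_generation: 95
    target_subpops: [2]
    focal_founder_freq: 0.01
qc:
  pca_k: 10
drc:
  # on a 40-cM chromosome the swept region is a sizable fraction of all
  # bins, so the empirical-null exclusion level is set to 1% rather than
  # the genome-scale Bonferroni default
  alpha_exclude: 0.01
  # IBD detection on a subset of haplotypes keeps the pair count tractable
  max_haplotypes: 240
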