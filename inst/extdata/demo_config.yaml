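# End-to-end synthetic demo: simulate profiles, AS events and an EMSA
# titration, then run all three analyses on the simulated inputs.
seed: 42
out_dir: demo_out
stages:
  profiles:
    n_species: 60
    n_background: 300
    module_size: 8
    lambda: 1
    rho: 0.8
  events:
    n_genes: 80
    frac_u12_genes: 0.3
    n_events: 600
    aa_enrichment_fold: 3
  emsa:
    kd_true: 2.14
    noise_sd: 0.02
    n_replicates: 3
  coevolve:
    k: 10
  splice:
    pr_min: 0.9
    dpsi_min: 0.05
  fit: {}
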