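# Demo configuration: HDLSS stage series from the default planted-DNB model.
simulate:
  n_genes: 500
  dnb_size: 10
  intra_coupling: 20
  schedule: [0.1, 0.3, 0.5, 0.7, 0.95]
  n_samples: 8
  meas_noise_sd: 0.1
  noise_scale: 1.0
  seed: 42
detect:
  sd_fold_min: 1.0
  corr_link_min: 0.9
  min_module_size: 6
  peak_ratio_min: 2
rank:
  k: 10
  select: topk
intervene:
  strength: 0.5
  n_draws: 100
  seed: 7
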