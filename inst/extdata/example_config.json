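{
  "methods": ["1TCM", "SRTM2-pop", "SRTM2-coupled", "SRTM", "Logan"],
  "k2_prime": 0.037,
  "t_star": 30,
  "truncation_grid": [40, 60, 80, 90, 100],
  "n_hc": 3,
  "n_pd": 5,
  "noise_scale": 0.05,
  "seed": 101
}
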