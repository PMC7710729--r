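# Example three-population demography (African-like founder, European-like
# and Asian-like daughters). Sizes are reduced and per-bp rates raised so
# that theta = 4*N*mu and rho = 4*N*r per bp stay at a human-like 5e-4 while
# simulation stays cheap. All quantities are per generation.
mu: 1.05e-6         # per bp per generation
recomb: 1.05e-6     # per bp per generation
length_bp: 300000
n_generations: 1560 # 1200 generations (10 N) of burn-in before the splits
populations:
  - id: AFR
    epochs: [{gen: 0, size: 120}]
    sample: 40
  - id: EUR
    origin: AFR
    split_gen: 1200
    epochs: [{gen: 1200, size: 80}]
    sample: 20
  - id: EAS
    origin: EUR
    split_gen: 1320
    epochs: [{gen: 1320, size: 80}]
    sample: 20
migration:
  - {dest: AFR, src: EUR, rate: 5.0e-5}
  - {dest: EUR, src: AFR, rate: 5.0e-5}
  - {dest: EUR, src: EAS, rate: 5.0e-5}
  - {dest: EAS, src: EUR, rate: 5.0e-5}
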