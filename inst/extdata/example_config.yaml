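# Example configuration for the delaykin CLI and load_config().
# Every block is optional; omitted fit entries fall back to the default
# starting point and bounds.

kernel:
  a: 1.255818        # rate parameter of the delay density (1/s)
  m: 6.703709        # shape parameter (dimensionless)
  tau_min: 4.673685  # minimal complex lifetime (s)

model:
  family: es_distributed
  kd: 0.04042714     # bimolecular rate constant (1/(mg/mL)/s)

fit:
  init: [0.04, 1, 20, 5, 6000, 50]          # (kd, a, m, tau_min, lambda0, K)
  lower: [1.0e-10, 1.0e-10, 1.0e-10, 1.0e-4, 1.0e-10, 1.0e-10]
  upper: [1, 1000, 1000, 1000, 1.0e+6, 1.0e+6]
  xi: 1000           # bound-violation penalty weight
  max_iter: 800      # simplex iterations per start

protocol:
  duration: 500      # s
  period: 5          # s between samples
  addition_time: 250 # substrate added at this time (s)
  base_volume: 4.0   # mL of BSA solution
  enzyme_stock: 2    # mg/mL
  enzyme_volume: 0.1 # mL
  substrate_stock: 2 # mg/mL
  doses: [0.1, 0.3, 0.9, 1.5]  # mL
  baseline: 550      # instrument units
  noise_sd: 0
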