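# spinflex run configuration template.
# All randomness derives from `seed`; analysis defaults shown explicitly.
seed: 1
mc_replicates: 500
error_floor: 0.02            # fractional peak-height error floor
threshold_sigma_factor: 1.5  # CSP rule: trimmed mean + k * sigma
trim_fraction: 0.1           # trimmed from EACH tail
weights:
  W_N: 0.101
  W_C: 0.251

stages:
  simulate:                  # synthetic inputs; omit to analyze real files
    relax:
      r1:    [1.0, 1.1, 0.9, 2.2, 1.05]
      r1rho: [20, 21, 19, 35, 20.5]
      noise: 0.02
    noe_preset: N68_K
    csp:
      n_residues: 20
      perturbed:
        residue: [3, 9]
        d_H: [0.30, 0.25]
        d_X: [2.0, 2.2]
      noise_ppm: 0.002
    cluster_preset: L48a_K
    cpmg_preset: nak_na_sf
  fit_relax:
    omega_sl: 1923           # spin-lock field, Hz
    offset: 0                # global offset from the 15N carrier, Hz
  noe: {}
  csp: {}
  populations:
    n_states: 3
    init_positions: [[0.30, 24.0], [0.40, 24.25], [0.20, 23.8]]
  cpmg:
    fit: true
  report: {}
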