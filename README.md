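# spinflex

Per-residue analysis of protein dynamics by solution NMR, built for the
kind of study that asks how an ion channel's selectivity filter moves on
different timescales under different ions. The package covers four
quantitative layers and a synthetic-data generator that makes every layer
testable without spectrometer data:

* **ps–ns motions** — ¹⁵N R1 and R1ρ decays fit to I₀e^(−Rt) with Monte
  Carlo errors, R1ρ → R2 offset correction
  (R₂ = R₁ρ/sin²θ − R₁/tan²θ, θ = tan⁻¹(ω/Ω)), and heteronuclear NOE
  I_sat/I_ref with propagated errors; deviations from a helical baseline
  flag flexible residues.
* **Slow structural change** — chemical shift perturbations
  CSP = √(Δδ_H² + (W·Δδ_X)²) with W_N = |γ_N/γ_H| = 0.101,
  W_C = |γ_C/γ_H| = 0.251, thresholded at 1.5σ above the 10% trimmed mean.
* **Conformational heterogeneity** — fractional state populations of
  overlapped multi-state resonances by 2D Lorentzian lineshape
  deconvolution (volume shares).
* **µs–ms exchange** — CPMG relaxation dispersion: R2,eff(ν) =
  −ln(I(ν)/I₀)/T_relax with replicate-pooled errors, endpoint Rex
  estimates, exact two-state propagators for ¹³C multiple-quantum and ¹H
  single-quantum coherences, and global χ² fits sharing k_ex and p_b
  across probes and static fields (Carver–Richards and Luz–Meiboom closed
  forms included as cross-checks).

Inputs are plain text: Sparky-style peak lists, TSV/CSV series and shift
tables, YAML run configuration. Outputs are CSV tables, Chimera-style
per-residue attribute files for structure coloring, and a JSON run
summary with file digests.

## Worked example

```r
library(spinflex)

# --- R1 from a synthetic 5-delay decay (true R = 1.3 s^-1, 2% noise)
ser <- gen_decay_series(R = 1.3, I0 = 1e5, noise_fraction = 0.02,
                        seed = 7, residue_id = 68L)
fit <- fit_exponential(ser)
fit <- monte_carlo_error(ser, fit, n_mc = 500, seed = 7)
sprintf("R1 = %.3f +/- %.3f s^-1", fit$rate, fit$rate_error)
#> "R1 = 1.223 +/- 0.072 s^-1"

# --- heteronuclear NOE from a saturated/reference pair (true 0.43)
pair <- gen_noe_pair(0.43, seed = 1)
noe <- compute_noe(pair$sat, pair$ref)
sprintf("NOE = %.3f +/- %.3f", noe$noe, noe$noe_error)
#> "NOE = 0.425 +/- 0.022"

# --- three-state methyl cluster, populations 0.86/0.07/0.07
pr <- spinflex_preset("L48a_K")
g  <- gen_peak_cluster(pr$positions, pr$linewidths, pr$populations,
                       pr$grid, pr$noise_fraction, seed = 1)
quantify_populations(g, 3, init_positions = pr$positions)$populations
#> 0.860 0.069 0.071
```

The R1 estimate sits about one propagated SD from the generating value and
the major-state population is recovered to 0.1 points — the error bars are
calibrated, not decorative (the test suite checks both claims). The CSP
threshold helper prints its convention alongside the number:

```r
significance_threshold(csp_values)$rule
#> "trimmed mean (0.1 from each tail) + 1.5 * SD of trimmed set"
```

An end-to-end run (simulate → fit → report) is driven by one config:

```r
run_pipeline("run.yaml", out_dir = "results/run1")
```

producing `rates.csv`, `r2.csv`, `noe.csv`, `csp.csv` + `csp.attr`,
`populations.json`, `rex.csv`, `report.csv` and `run_summary.json`; see
`inst/extdata/run.yaml` for a template.

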