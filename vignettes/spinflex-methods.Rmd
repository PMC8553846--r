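---
title: "Models and methods behind spinflex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spinflex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinflex)
```

spinflex implements a per-residue NMR dynamics workflow of the kind used to
characterize ion-channel selectivity filters in solution: spin relaxation
(R1, R1&rho;, heteronuclear NOE) for ps–ns motions, chemical shift
perturbation (CSP) mapping between two ionic conditions, multi-state peak
population quantification, and CPMG relaxation dispersion with two-state
exchange fitting for &mu;s–ms motions. This vignette explains the models,
the tunable parameters, the numerical choices, and what the synthetic-data
tests do and do not demonstrate.

## Spin relaxation

Relaxation decays are fit to the mono-exponential $I(t) = I_0 e^{-Rt}$ by
weighted nonlinear least squares (Levenberg–Marquardt via minpack.lm), with
weights $1/\sigma_i^2$ from the stated intensity errors. No
multi-exponential model is offered: for well-resolved amide decays the
mono-exponential is adequate and a more complex model is rarely
statistically justified. Start values are deterministic — $I_0$ from the
maximum intensity and $R$ from a log-linear regression of the positive
intensities (clamped at zero so flat series start at $R = 0$) — so a fit is
reproducible without a random initialization.

Peak-height errors carry a configurable **fractional floor** (default 2% of
the height): base-plane noise estimates below the floor are raised to it.
Parameter uncertainties come from Monte Carlo resampling (default 500
replicates): each intensity is redrawn from a Gaussian centred on the
*measured* value — not on the fitted curve, a deliberate convention choice
that keeps the error estimate honest when the model is slightly wrong — with
SD equal to its stated error, the series is refit, and the SD of the
replicate estimates is reported. The suite verifies that a 500-replicate
error agrees with a 10,000-replicate re-simulation from the true curve
within 15%.

R1&rho; is converted to R2 with the offset correction
$R_2 = R_{1\rho}/\sin^2\theta - R_1/\tan^2\theta$, where
$\theta = \tan^{-1}(\omega/\Omega)$ is the effective-field tilt from the
spin-lock strength $\omega$ (e.g. 1923 Hz) and resonance offset $\Omega$.
The offset can be supplied globally or per residue; which was used is
recorded in the run summary. The error is first-order propagation treating
$R_{1\rho}$ and $R_1$ as independent; a Monte Carlo cross-check in the test
suite confirms the linearization to within 5% at typical uncertainties.

The heteronuclear NOE is the ratio of saturated to reference peak heights,
$\mathrm{NOE} = I_{sat}/I_{ref}$, with the standard error propagation
$\sigma = |\mathrm{NOE}|\sqrt{(\sigma_{sat}/I_{sat})^2 +
(\sigma_{ref}/I_{ref})^2}$. Because the propagated error is a 1&sigma;
quantity, recovery checks treat $\pm 1.96\sigma$ as the 95% interval; the
generator tests confirm the empirical coverage.

Residues with enhanced ps–ns dynamics are flagged against a **helical
baseline**: mean ± SD of R1 and NOE over residues annotated as helical,
flagging residues with R1 above and NOE below the baseline by more than
$k$ SD jointly (default $k = 2$). The flag set is invariant under adding a
constant to all values, since both baseline and values shift together.

## CSP mapping and the significance rule

The weighted CSP is $\sqrt{\Delta\delta_H^2 + (W\,\Delta\delta_X)^2}$ with
$W = |\gamma_N/\gamma_H| = 0.101$ for amides and
$|\gamma_C/\gamma_H| = 0.251$ for methyls (three-decimal truncation of the
gyromagnetic-ratio magnitudes; `csp_weights_from_gamma()` recomputes them
from the constants). Carbonyl and C&alpha; differences are reported
unweighted and signed; thresholding uses magnitudes.

The significance threshold is the **10% trimmed mean plus 1.5&sigma;**:
`floor(0.1 n)` values are dropped from *each* tail, and &sigma; is the SD
of the trimmed set. Both conventions (per-tail trimming; trimmed-set
&sigma;) are genuinely open choices and are recorded in the output's `rule`
string so alternates can be compared. Two consequences worth knowing:
the rule is robust to the very outliers it is meant to detect (the trimmed
statistics barely move when a large perturbation is added), and under a
pure-noise null it flags roughly 17% of residues — it is a lenient
descriptive rule, not a controlled hypothesis test. Peaks present in only
one condition are reported as *not comparable*, never as CSP = 0; when a
residue shows minor-state resonances in one condition, the major state's
position enters the CSP and minor states are listed separately.

## Multi-state peak populations

Overlapped clusters are deconvolved as sums of 2D Lorentzians
$A\,/\,[(1 + ((x-x_0)/w_x)^2)(1 + ((y-y_0)/w_y)^2)]$ with per-component
position, half-widths and amplitude, fit by Levenberg–Marquardt from
user-supplied (or preset) starting positions. Fractional populations are
component volume shares, with volume $= A \pi^2 w_x w_y$ analytically;
heights are biased by overlap, so volume is the default and height-share is
available as a mode. Populations are invariant under uniform intensity
scaling, and negative fitted amplitudes are an error rather than silently
truncated. Whether the emulated measurements used heights, volumes or
lineshape fits is not knowable from summary figures alone; both modes exist
for that reason.

## CPMG dispersion and two-state exchange

R2,eff is computed from intensities as
$-\ln(I(\nu)/I_0)/T_{relax}$. Replicate &nu; points are pooled: the value
is their mean, and the error is the replicate SD pooled across all
replicated groups of the curve (square root of the mean within-group
variance), applied to every point. A per-pair SD has one degree of freedom
and can collapse to zero, which would produce degenerate $1/\sigma^2$ fit
weights; pooling across groups is the stable version of
error-from-replicates. The fractional intensity-error floor carries over:
a 2% floor on $I$ maps onto $R_{2,eff}$ as $0.02/T_{relax}$, and
replicate-derived errors are never taken below it — the dispersion
analogue of the peak-height floor convention. Without the floor,
occasional optimistic replicate draws produce overconfident weights and
visibly biased exchange fits. The endpoint exchange estimate
$R_{ex} = R_{2,eff}(\nu_{min}) - R_{2,eff}(\nu_{max})$ carries the caveat,
propagated into the output, that subtracting two points underestimates the
error relative to fitting the whole curve. An alternative reading of the
endpoint rule as a raw intensity difference is available behind a flag.

**Pulse-train convention.** $\nu_{CPMG} = 1/(2\delta)$ with $\delta$ the
spacing between successive 180&deg; pulses, so a period $T_{relax}$ contains
$n = 2\nu T$ pulses. The shipped grids (including the 33.33/66.67/133.33 Hz
values at $T = 30$ ms) all give even integer $n$ under this convention;
non-conforming grids are rejected.

**Two-state models.** Exchange between a major state A and minor state B
($k_{AB} = p_b k_{ex}$, $k_{BA} = (1-p_b)k_{ex}$) is propagated through the
pulse train as a 2×2 complex evolution problem in the state-A rotating
frame, using exact closed-form matrix exponentials per half-element and
matrix powers over repeated cycles. For ¹H–¹³C **multiple-quantum**
coherence the active offset of state B combines both nuclei,
$\Delta\omega_H \pm \Delta\omega_C$; each ¹³C 180&deg; pulse conjugates
only the carbon part of the phase (sign alternation), and the two
coherence-transfer pathways are averaged. A physical consequence built into
the model: the ¹H part of the MQ phase is *never* refocused by the ¹³C
pulse train, so a large methyl $\Delta\omega_H$ flattens the observable
dispersion — which is why the shipped presets keep methyl
$\Delta\omega_H$ small (0.02–0.04 ppm). For ¹H **single-quantum**
coherence the 180&deg; pulses conjugate the full magnetization and only
$\Delta\omega_H$ is active. Detection is the state-A component magnitude
normalized by its initial value, matching how a reference-normalized peak
intensity is measured; R2,eff is exact for &delta;-function pulses. The
exchange-free rate $R_{2,0}$ (equal in both states) adds exactly and is
profiled out analytically in fits.

Both propagators are validated in the test suite against an independent
fine-step RK4 integrator of the same two-state evolution to within
0.05 s⁻¹ (observed agreement ~10⁻¹¹). The Carver–Richards closed form is
provided (`method = "cr72"`) and agrees with the propagator in the
fast-intermediate regime and with the Luz–Meiboom expression in fast
exchange within 1%; it is the dominant-eigenvalue approximation, however,
and deviates by up to a few s⁻¹ in slow-intermediate exchange, so the exact
propagator — not CR72 — is the default SQ model and the one used in fits.

**Global fitting.** `fit_dispersion_global()` minimizes the joint
&chi;² with $k_{ex}$ and $p_b$ shared across the group, per-probe
$\Delta\omega$ (constrained non-negative — the sign is unidentifiable from
CPMG data alone, and the reported ambiguity note says so) and per-curve
$R_{2,0}$ profiled analytically. Parameters are optimized on transformed
scales ($\log k_{ex}$, logit of $2p_b$, $\log \Delta\omega$) from a
multi-start grid over $(k_{ex}, p_b)$, polished by Nelder–Mead;
uncertainties come from the &chi;² curvature (central-difference Hessian,
eigenvalue-clamped, delta method back to natural scale). A flat-model
comparison flags groups with no detectable exchange, and a reduced &chi;²
well above 1 is surfaced as a warning that two-state exchange may be
inadequate (multi-state behaviour). Only two-state exchange is modelled;
populations are deliberately not interpreted from dispersion data alone.

## Synthetic data: what it emulates, and what it does not

Each generator reproduces the statistical structure the corresponding
analysis assumes: exponential decays with Gaussian intensity noise and the
2% error floor; saturated/reference pairs sharing absolute base-plane
noise; dispersion intensities $I_0 e^{-R_{2,eff}T}(1+\varepsilon)$ with
independent noise on replicates; clusters of 2D Lorentzians with volumes
proportional to populations; and paired shift tables with a planted
perturbed set. Every generator derives its random substream from
(seed, label), so adding a generator never perturbs existing draws, and
all outputs are bit-reproducible under a fixed seed.

Named presets freeze the study conditions. Quantities the emulated
measurements pin down are encoded directly (exchange rates 390 and
356 s⁻¹; populations 0.86/0.07/0.07 and 0.47/0.37/0.16; NOE 0.43; the
&nu; grids and relaxation periods; 2% intensity noise). Quantities they do
not pin down are labelled *assumed* in the preset metadata and were chosen
once on physical grounds: $p_b = 0.05$, $R_{2,0} = 20$ s⁻¹, linewidths
typical of methyl resonances, and per-probe $\Delta\omega$ calibrated so
the model's endpoint $R_{ex}$ reproduces the reported per-probe magnitudes
(~15 Hz for the V64-like probe, ~4 Hz for the V59-like probe at 800 MHz).
Assumed values are never used as reference values in tests.

What passing tests show: the estimators are unbiased and correctly
calibrated *under the generators' assumptions* — Gaussian noise,
mono-exponential decays, exactly two exchanging states, Lorentzian
lineshapes, known component counts. What they do not show: robustness to
spectral artifacts, baseline distortions, overlapping interfering signals
(e.g. residual lipid resonances), multi-state exchange, or peak-picking
errors, none of which the generators simulate. At the preset noise level
the pairwise exchange-rate fit has a standard error of roughly
40–110 s⁻¹ — comparable to the reported ±47 s⁻¹ — so individual synthetic
realizations scatter accordingly; recovery is asserted within three
standard errors, not as a point match.

## Problem sizes and runtime choices

The shipped analyses are desk-scale by construction: five-delay relaxation
series; 20–22-point dispersion grids at two fields for two probes
(~80 R2,eff points per global fit); 121×101 cluster grids; 500 Monte Carlo
replicates by default (tests use fewer where the quantity under test does
not depend on replicate count). A full global dispersion fit takes tens of
seconds in plain R; the propagator caches each element pair and uses matrix
powers, so cost grows with the number of distinct &nu; values, not with
$\nu T$.

## Known limitations

* Two-state exchange only; evidence of more states appears solely as a
  goodness-of-fit warning.
* The MQ model assumes ideal &delta;-function pulses and equal intrinsic
  relaxation in both states; off-resonance pulse effects are not modelled.
* The CSP significance rule is descriptive, with a substantial nominal
  false-positive mass by design.
* Population deconvolution requires the number of states and approximate
  starting positions; it does not discover components.
* Peak lists and shift tables are assumed pre-assigned; no peak picking or
  assignment transfer is performed.
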