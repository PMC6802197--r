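# intadyn

Single-molecule and ensemble analysis of retroviral intasome–target DNA
dynamics.

Retroviral integration is catalyzed by the intasome, a multimeric
integrase–viral-DNA nucleoprotein machine that captures host target DNA
(the target capture complex, TCC) and covalently joins both viral ends
into it (the strand transfer complex, STC). `intadyn` implements the
computational analysis used to characterize this reaction with magnetic
tweezers (MT), atomic force microscopy (AFM) and bulk integration assays
on supercoiled plasmid targets:

- **DNA mechanics** — closed-form free energies: supercoiling
  ΔG_SC = (1100/N)·k_BT·ΔLk², harmonic bending ΔG = A·k_BT·θ²/(2l),
  interface stability ΔG = k_BT·ln(τ_bound/τ_unbound), the Bell model
  τ(F) = τ₀·exp(−F·Δx/k_BT), the plectonemic Δz ↔ ΔLk conversion, and the
  AFM tip-convolution width FWHM = D + h·tan α.
- **Trace analysis** — an unbiased iterative chi-square step finder with
  counter-fit quality control for MT extension traces, and the moving
  window fluctuation statistic σ_z.
- **Dwell statistics** — exponential lifetime MLE with exact chi-square
  95% confidence intervals, kernel-density analysis of released-turn
  quantization with a periodicity spectrum, Kolmogorov–Smirnov and
  per-trace Welch comparisons.
- **Force spectroscopy** — survival curves of forced STC disassembly,
  per-force exponential lifetimes, and the weighted log-linear Bell fit
  returning the zero-force lifetime and distance to the transition state.
- **Ensemble kinetics** — the target → TCC → half-site → full-site
  reaction scheme with an active-intasome fraction, integrated as an ODE
  system and fitted globally across plasmid lengths by error-weighted
  Levenberg–Marquardt least squares, plus identifiability profiles.
- **AFM statistics** — plasmid topology classification by self-crossing
  number (open circular for n ≤ 6), count fractions with √k/n errors,
  proportion tests and circular entry/exit-angle statistics.
- **Synthetic data** — seeded generators for every input the pipeline
  consumes (capture traces, supercoil-release staircases, force-jump
  rupture tables, kinetics tables, AFM particle tables), each returning
  its ground truth so that recovery can be scored.

## Worked example

Simulate a target-capture trace at the camera rate of 58 Hz, decompose it
into steps, and estimate the interface lifetime:

```r
library(intadyn)

cfg <- sim_config(seed = 7, duration_s = 320, noise_sd_nm = 8)
sim <- simulate_tcc_trace(cfg, tau_tcc_s = 3, min_step_nm = 24)
fit <- find_steps(sim$trace)
fit
#> step fit: 105 steps (ok), counter-fit quality 45.7
#>   |step| median 52.8 nm, dwell median 2.03 s

fit_exponential_mle(fit$dwell_times_s)
#> exponential lifetime: tau = 2.84 [2.365, 3.476] (95% CI, n = 104)
```

The step finder recovers the repositioning events of the bound intasome;
the dwell-time MLE returns the auxiliary-interface lifetime with its
chi-square confidence interval, here covering the generating 3 s.

Force spectroscopy of STC disassembly:

```r
tab <- simulate_force_jump(sim_config(seed = 11), tau0_days = 245,
                           delta_x_nm = 0.89, forces_pN = c(30, 40, 50),
                           n_per_force = 55)
fit_bell(fit_force_lifetimes(tab, "final"))
#> Bell-model fit of force-dependent lifetimes
#>   tau(F=0) = 2.65e+07 +/- 1.1e+07 (same unit as input lifetimes)
#>   delta x  = 0.901 +/- 0.042 nm (9.01 +/- 0.42 Angstrom)
#>   T = 298 K, n-weighted fit over 3 forces
```

The whole pipeline (simulation → step finding → dwell statistics → Bell
fit → kinetic fit → AFM census) runs from a YAML configuration:

```r
demo <- system.file("extdata", "demo_config.yaml", package = "intadyn")
report <- run_pipeline(demo, out_dir = "results")
```

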