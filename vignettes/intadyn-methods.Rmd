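---
title: "Models and methods behind intadyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind intadyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intadyn)
```

`intadyn` analyses single-molecule magnetic-tweezers (MT) recordings,
AFM particle measurements and bulk kinetics of retroviral intasomes
reacting with supercoiled target DNA. This vignette describes the models
the package implements, the assumptions behind them, the synthetic-data
generators used in place of raw experimental recordings, and the
numerical and design choices a maintainer should know about.

## DNA mechanics

Four closed-form results anchor the energetics:

* **Supercoiling.** A plasmid of $N$ base pairs carrying a linking
  difference $\Delta Lk$ stores
  $\Delta G_{SC} = (1100/N)\,k_BT\,\Delta Lk^2$. The relaxed linking
  number is $Lk_0 = \mathrm{round}(N/10.5)$ — rounding to an integer is
  required for a covalently closed circle, and it is the convention that
  makes a 4361 bp plasmid at $\sigma = -0.05$ carry
  $\Delta Lk = 0.05 \times 415 = 20.75$ turns and
  $\Delta G_{SC} \approx 110\,k_BT$.
* **Bending.** The harmonic worm-like-chain penalty for bending a
  segment of length $l$ by $\theta$ is
  $\Delta G = A\,k_BT\,\theta^2/(2l)$ with persistence length
  $A = 40$ nm. Segment lengths are given in base pairs and converted at
  0.34 nm/bp (so the 60° bend over 14 bp engaged in the active site
  costs 4.6 $k_BT$, and a 10° pre-bend, as present in plectonemic DNA,
  costs 0.13 $k_BT$). `prebend_corrected_penalty()` subtracts the
  pre-bend term.
* **Interface stability.** A DNA-binding interface observed to spend
  $\tau_\mathrm{bound}$ bound and $\tau_\mathrm{unbound}$ unbound
  contributes $\Delta G = k_BT \ln(\tau_\mathrm{bound} /
  \tau_\mathrm{unbound})$.
* **Force dependence.** Bond lifetimes under tension follow the Bell
  model $\tau(F) = \tau_0\exp(-F\Delta x / k_BT)$ with $\Delta x$ the
  distance to the transition state.

Angles cross the API in degrees and are converted to radians internally.
Energies are reported in $k_BT$ carrying the temperature they were
computed at (bulk reactions 310 K; the MT experiments are modelled at
room temperature, 298 K, since the flow-cell temperature is not
otherwise specified — both temperatures are explicit parameters, so the
choice is testable). Conversion to kJ/mol is available but never
implicit. In the plectonemic regime the tether extension is linear in
the linking difference; the slope defaults to 45 nm/turn and is a
parameter of `mech_params()` rather than a derived quantity.

## Synthetic data: what it emulates and what it does not

No raw recordings are distributed with the studies this package targets,
so every pipeline input is produced by a seeded generator that also
returns its ground truth:

* `simulate_tcc_trace()` renders target capture by a catalytically
  blocked intasome: a bare-DNA period, a capture event that reduces the
  per-sample extension noise (DNA bridging pinches off part of the
  plectoneme), and a piecewise-constant staircase of repositioning steps
  with exponential dwells (default mean 3 s) and two-sided exponential
  step sizes (decay length 45 nm). A lower truncation on the step
  magnitude (`min_step_nm`) lets benchmarks fix the signal-to-noise
  ratio.
* `simulate_relaxation_trace()` renders stepwise supercoil release from
  an STC: plateau dwells are exponential (the apical-interface
  lifetime), and each unbinding event releases a geometric number of
  turns — the interface has a fixed probability of reforming after every
  released turn — converted to extension at the plectonemic slope and
  rendered as a finite-speed ramp at 4 ms/turn so that step finding is
  exercised on non-instantaneous steps.
* `simulate_force_jump()` draws rupture times per force from the Bell
  model, with an optional earlier loop-release event (its own Bell
  parameters) whose extension jump is proportional to the tether's
  fluctuation-reduction depth.
* `simulate_ensemble_kinetics()` integrates the kinetic model below and
  adds Gaussian noise to the full-site fraction, returning means and SDs
  over replicates (default 3, matching the bulk assay design of three
  repeats). The default sampling times (0–240 min, 6 points) and noise
  SD (0.05) are chosen as typical of gel-based quantification.
* `simulate_afm_particles()` draws integer self-crossing counts from
  rounded Gaussians truncated at zero (rejection), with class means 2.4
  (open circular) and 12.2 (supercoiled) and common SD 1.7.

The generators reproduce the *statistical structure* the analysis
assumes — exponential dwells, geometric turn releases, Bell-distributed
rupture times, Gaussian sampling noise. They deliberately do not model
bead Brownian dynamics, camera tracking, drift, or the worm-like-chain
force-extension relation beyond the linear plectonemic slope. Passing
recovery tests therefore demonstrates correctness of the estimators
under the model assumptions, not robustness to instrument artefacts such
as drift or tracking noise correlations. Torque asymmetry between
positive and negative supercoils is represented by letting the lifetime
and rebinding probability differ between conditions, not by computing
torque from first principles.

## Step finding

`find_steps()` implements iterative chi-square step fitting with
counter-fit quality control. At each iteration the single step that
maximally reduces the residual sum of squares is placed (ties break to
the earliest index, making the fit deterministic); this yields a nested
sequence of candidate fits. The candidate with $k$ steps is scored by
the ratio of the residuals of its *counter-fit* — steps forced to the
plateau centres, the worst placement consistent with $k$ steps — to its
own residuals; the accepted $k$ maximizes this ratio, and the whole fit
is rejected (zero steps) if the ratio never reaches the acceptance
threshold (default 1.3).

Two guards shape the candidate set. Steps are never placed closer than
the minimum dwell (default 3 samples at 58 Hz). And candidate growth
stops once the best available reduction falls below a BIC-style penalty
$2\hat\sigma^2 \ln n$, with $\hat\sigma$ estimated robustly from first
differences (median absolute deviation): without this, unconstrained
greedy growth slowly inflates the counter-fit ratio on step-free noise
and the threshold rule loses its null calibration. On noise-free
staircases the penalty vanishes and recovery is exact to machine
precision.

Samples recorded while the magnets are being rotated can carry commanded
extension changes; steps detected where the `magnet_turns` channel is
changing are masked out (`mask_rotation = TRUE`). Steps smaller than
`min_step_nm` are merged away, smallest first.

The fluctuation statistic $\sigma_z$ is the sample SD in a centred
0.5 s moving window, truncated at the trace edges.

## Dwell and step-size statistics

For exponential dwells the MLE of the mean is the sample mean; with a
detection cutoff the samples are treated as left-truncated and the MLE
becomes the mean excess (memorylessness). The 95% CI uses the exact
chi-square pivot $2n\hat\tau/\tau \sim \chi^2_{2n}$; a bootstrap
interval is available as a cross-check. The final, interrupted dwell of
a trace is simply discarded rather than right-censored — at the sample
sizes involved the bias is negligible compared with the CI width.

Released-turn samples are summarized by a Gaussian KDE with the narrow
bandwidth of 0.2 turns on a fixed 0.05-turn grid (evaluated exactly, not
via FFT binning, so the bandwidth and grid are precisely as stated);
integer quantization of released turns appears as local maxima at
integer positions. The periodicity spectrum fits and subtracts a single
exponential background, then reports the dominant discrete-Fourier
frequency above 0.25 cycles/turn (excluding the DC/slow-background
band); integer quantization gives a dominant peak at 1 cycle/turn.

Distribution comparisons between conditions (torque sign, supercoil
chirality) use the standard two-sample Kolmogorov–Smirnov test with
asymptotic p-values. Fractions of large release steps are computed per
trace and compared across conditions with a Welch t-test on the
per-trace fractions — pooling events across tethers would break
independence.

## Force spectroscopy

Rupture times at each force are fitted by the exponential MLE; the Bell
fit is a weighted linear regression of $\ln\tau$ on $F$ whose slope is
$-\Delta x/k_BT$ and intercept $\ln\tau_0$. Because the variance of
$\ln\hat\tau$ for an exponential sample is $1/n$, the weights default to
the per-force sample sizes; an unweighted fit is provided for
sensitivity analysis. All probing forces lie far above $k_BT/\Delta x$,
so $\tau_0$ is an extrapolation: its relative standard error exceeds
that of $\Delta x$ (a property the test suite asserts), which is why a
zero-force lifetime from such an experiment should be read as
order-of-magnitude. Tether-handle detachment can be emulated in the
simulator as a competing risk; labelled handle ruptures are excluded
from the STC fit, consistent with treating the fitted zero-force
lifetime as a lower limit.

## Ensemble kinetic model

The bulk assay observes the fraction of full-site (linearized) product
over incubation time for plasmids of several lengths. The model is the
minimal linear scheme

$$ T \xrightarrow{k_{on}} C \xrightarrow{k_{hs}} H
   \xrightarrow{k_{fs}} F $$

under pseudo-first-order conditions (intasome in excess, so the intasome
concentration is absorbed into $k_{on}$), with TCC dissociation
$k_{off}$ fixed at the negligible $10^{-10}\,\mathrm{min}^{-1}$. Only
the fraction $f_\mathrm{active}$ of intasomes is catalytically
competent; capture by an inactive intasome is a dead end that still
sequesters the target. Internally the captured pool is therefore split
into an active branch (entered at rate $k_{on} f_\mathrm{active}$, the
only one that proceeds to half- and full-site) and an inactive branch.
This makes the long-time full-site amplitude equal $f_\mathrm{active}$ —
which is precisely what renders $f_\mathrm{active}$ identifiable
alongside $k_{on}$: had the active fraction entered only as a rate
multiplier, the data would constrain just the product
$k_{on} f_\mathrm{active}$ and the fit would be degenerate.

`integrate_model()` solves the system numerically (lsoda, tolerances
$10^{-10}$); the test suite checks it against the closed-form
three-exponential (Bateman) solution of the irreversible chain to
$10^{-8}$. The optimizer uses an exact Bateman fast path when
$k_{off} t_\mathrm{max} < 10^{-6}$ (nudging near-coincident rates apart
by a relative $10^{-6}$ to avoid cancellation) and falls back to the ODE
otherwise.

`global_fit()` shares $f_\mathrm{active}$, $k_{hs}$, $k_{fs}$ across
plasmid lengths, fits one $k_{on}$ per length, and minimizes the
error-weighted sum of squares by Levenberg–Marquardt. Three numerical
choices matter:

* **Weights.** Per-point SDs estimated from three replicates carry
  roughly 50% relative error, and $1/\mathrm{SD}$ weighting is then
  dominated by points with accidentally tiny SDs. The default pools the
  SD per plasmid length (root mean square), which keeps the error
  weighting across lengths while restoring calibrated weights;
  `weights = "per_point"` gives the literal per-point behaviour.
* **Exchange symmetry.** The full-site fraction is *exactly* invariant
  under swapping $k_{hs}$ and $k_{fs}$ (the Bateman solution is
  symmetric in the chain rates), so the data determine the pair only up
  to relabelling. Fits are reported in the canonical order
  $k_{hs} \ge k_{fs}$, and the default start (0.2 and 0.05 min$^{-1}$)
  deliberately breaks the symmetry — starting with equal rates places
  the optimizer exactly on the symmetric ridge, where the Jacobian is
  singular.
* **Starts.** Besides the deterministic default start
  ($f_\mathrm{active} = 0.5$, $k_{on} = 0.1$), a data-driven start
  (amplitude from the largest observed fraction, capture rates from the
  time to half-amplitude) and seeded log-normal perturbations are tried;
  if the best residual sum still sits far above its chi-square
  expectation, a wider round of restarts is run. Standard errors come
  from the Gauss–Newton approximation at the optimum; intervals for the
  positive rates are Wald intervals in log space (their sampling
  distributions are right-skewed), with $t$ quantiles at the residual
  degrees of freedom. Two degenerate situations get special treatment:
  a rate driven to its upper bound is only bounded from below by the
  data (the corresponding step is effectively instantaneous), so its
  interval becomes one-sided with the lower limit from a
  profile-likelihood search; and when the $k_{hs}$ and $k_{fs}$
  intervals overlap, the labels are unresolved and the identified set
  for either named rate is the union of the two intervals, which is
  what the fit reports for both.

`profile_identifiability()` fixes one parameter on a grid and refits the
rest. On data generated without dissociation the $k_{off}$ profile is
flat below $\sim 10^{-4}\,\mathrm{min}^{-1}$ — the rationale for fixing
it — while the $k_{hs}$ profile is convex with its minimum at either
member of the generating pair (the exchange symmetry again).

## AFM statistics

Topology is classified from the number of DNA self-crossings: open
circular for $n \le 6$, covalently closed above. With the observed class
distributions (means 2.4 and 12.2, SD 1.7), the Gaussian tail mass
beyond the threshold predicts misassignment below 2% for open-circular
and below 1% for supercoiled molecules, which the classifier reproduces
on synthetic censuses. Count fractions carry the Poisson counting error
$\sqrt{k}/n_\mathrm{tot}$ ($k$ the category count — the package reads
the census-legend convention this way, since the raw count is the
Poisson variable). Two-proportion contrasts default to Fisher's exact
test, appropriate for the small censuses involved. Entry/exit angles of
DNA at the intasome are summarized by vector-mean circular statistics
(circular SD $\sqrt{-2\ln R}$); angles can be folded to $[0°, 180°)$
when the reference long axis is orientation-free.

## Problem sizes and determinism

The shipped tests and the acceptance script run at desk scale: capture
traces of a few hundred seconds at 58 Hz (tens of thousands of samples,
about a hundred events), 100-seed repetitions for the dwell-time and
Bell recovery studies, a 100-seed recovery study for the global kinetic
fit (4 lengths × 6 times × 3 replicates each), 500-seed calibration of
the KS type-I error, and 10,000 particles per class for the topology
classifier. Every stochastic routine takes an explicit seed and is
bitwise reproducible; `run_pipeline()` derives per-stage seeds from the
master seed and embeds them in its report.

## Known limitations

* The step finder assumes uniform sampling and white noise; correlated
  bead fluctuations or drift would require pre-whitening or detrending
  that the package does not perform (an optional linear detrend is the
  only concession).
* Dwell-time fitting is single-exponential by design; no multi-
  exponential or gamma model selection is offered.
* The kinetic scheme is the minimal linear chain; branching into
  directly released open-circular product, or supercoil-dependence of
  the half-site rate, is out of scope.
* The zero-force STC lifetime is an extrapolation over many decades and
  inherits the handle-rupture caveat above.
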