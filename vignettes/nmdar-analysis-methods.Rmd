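---
title: "Models and methods behind nmdartools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nmdartools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmdartools)
```

nmdartools implements the quantitative workflows used to characterize
NMDA-receptor (NMDAR) variants with truncated GluN2 C-terminal domains:
kinetic-model-based open-probability estimation from MK-801 block,
desensitization and dose-response fitting, neurosteroid modulation
indices, fluorescence quantification of surface expression and synaptic
localization, and the group-statistics stage. This vignette explains the
models, the assumptions behind them, the defaults, and the known
limitations — in particular what the synthetic-data generators do and do
not emulate.

## The four-state gating model

At a saturating glutamate concentration (1 mM) the receptor is doubly
liganded with very high probability, so agonist binding steps can be
lumped away. What remains is a linear four-state scheme

$$D \overset{k_r}{\underset{k_d}{\rightleftharpoons}} C
  \overset{k_o}{\underset{k_c}{\rightleftharpoons}} O
  \overset{k_b[\mathrm{MK}]}{\underset{k_u}{\rightleftharpoons}} B$$

with desensitized ($D$), closed ($C$), open ($O$) and MK-801-blocked
($B$) states. `rate_matrix()` assembles the generator $Q$ (columns sum
to zero, so probability is conserved); `propagate_states()` integrates
$\dot P = QP$ over an `application_protocol()`.

Key choices:

* **Initial condition.** Because agonist binding is not modeled, the
  receptor is held at $C = 1$ until glutamate onset and propagation
  starts there. This is the simplest assignment consistent with the
  lumped scheme; it also means the model says nothing about deactivation
  after agonist removal (current is simply gated off).
* **Propagation.** Within a protocol segment the generator is constant,
  so the solution is the matrix exponential. The implementation
  eigendecomposes the $4\times4$ generator once per segment and
  evaluates all sample times in one matrix product, falling back to
  stepwise `Matrix::expm()` when the eigenvector matrix is
  ill-conditioned. Tests verify agreement with a stiff ODE solver
  (`deSolve::lsoda`) to better than $10^{-6}$ absolute occupancy and
  probability conservation to better than $10^{-9}$.
* **Unblocking rate.** $k_u$ defaults to 0: on the tens-of-seconds
  timescale of a whole-cell recording MK-801 block is effectively
  irreversible. It is configurable for sensitivity analyses.
* **Recording chain.** `simulate_current()` maps open-state occupancy to
  an inward current at $-60$ mV, $I(t) = -\,\text{gain}\cdot O(t)$. With
  `filter_on = TRUE` it emulates the measurement chain: the MK-801
  concentration relaxes exponentially toward each segment's nominal
  value with the solution-exchange time constant (10 ms default), which
  feeds back into the generator; the current envelope is smoothed at
  glutamate transitions with the same constant; a 4-pole Bessel low-pass
  at 2 kHz is applied forward-only (the standard patch-clamp filter
  shape — the installed signal-processing library provides no Bessel
  designer, so the coefficients are derived from the 4th-order reversed
  Bessel polynomial and discretized by bilinear transform); and the
  result is resampled at 5 kHz. During the exchange transient the
  generator is time-varying and the propagator sub-steps at
  $\le 0.1$ ms. Analysis round-trip targets use the unfiltered path, so
  the filter emulation affects realism, not the headline numbers.

## Desensitization and the two-step open-probability estimate

`fit_desensitization()` fits the onset of desensitization with a single
exponential, $|I(t)| = I_{SS} + (I_P - I_{SS})e^{-(t-t_\text{peak})/\tau_d}$,
by unweighted least squares ($\tau_d$ bounded to (1 ms, 100 s),
initialized at one fifth of the window). The percent desensitization is
$D = 100\,(1 - I_{SS}/I_P)$, and the lumped rate constants follow as

$$k_d = D/\tau_d, \qquad k_r = (1 - D)/\tau_d,$$

with $D$ used as a *fraction* in these two identities — the only
dimensionally consistent reading when a percentage is printed elsewhere.
Peak detection applies a 3-sample median filter first, which leaves
noiseless traces untouched. The plateau of the fit is the default
$I_{SS}$; a last-decile mean is available (`measure_peak_ss(method =
"tail")`) because either convention is defensible for real recordings.

`estimate_po_two_step()` chains the two stages of the open-probability
estimate:

1. fit the control response (1 mM glutamate, no MK-801) for
   $\tau_d$ and $D$, giving $k_d$ and $k_r$;
2. fix $k_d$, $k_r$, fix $k_c = 200\ \mathrm{s^{-1}}$ (a conventional,
   deliberately arbitrary anchor) and $k_b = 25\ \mathrm{\mu M^{-1}s^{-1}}$,
   and fit the single free opening rate $k_o$ to the peak-normalized
   onset of MK-801 inhibition (`fit_ko()`). The objective is the RMS of
   the normalized current from the peak of the MK-801-condition response
   to the end of co-application; both the data and every candidate model
   trace are normalized to their own peaks. The scalar search runs on
   $\log_{10} k_o$ over $(10^{-3}, 10^4)\ \mathrm{s^{-1}}$ from three
   log-spaced restarts with a $10^{-10}$ objective tolerance; solutions
   at a bound are flagged.

The macroscopic open probability is then
$P_o = 100\,k_o/(k_o + k_c)$ (`po_from_rates()`).

Two properties are worth keeping apart. With $k_d, k_r$ fixed at their
generating values, the fit recovers $k_o$ essentially exactly (the
generator and the fitter share the model; tests require $< 0.5\%$ over
$k_o \in [5, 100]$). The full two-step estimate carries a documented
lumping bias: a single exponential is only an approximation to the
4-state relaxation (for wild-type-GluN2A-like rates the slowest
relaxation eigenvalue is $0.97\ \mathrm{s^{-1}}$ while $k_d + k_r =
1.06\ \mathrm{s^{-1}}$, and the measured plateau-to-peak ratio is 0.614
rather than the quasi-equilibrium 0.608), so the self-consistency test
uses a 15% relative band; in practice the bias is near 1–2%.

## Dose-response fitting

`fit_hill()` fits the logistic (Hill) equation
$I = 1/(1 + (\mathrm{EC_{50}}/[\text{agonist}])^h)$ per cell by
nonlinear least squares (start: geometric-mean concentration, $h = 1$;
bounds $\mathrm{EC_{50}} \in [10^{-3}, 10^4]\ \mathrm{\mu M}$,
$h \in [0.3, 5]$). Glutamate curves are measured in the continuous
presence of 30 µM glycine and glycine curves at 1 mM glutamate; the
functions validate this metadata. Pooling (`pool_fits()`) averages on
$\log_{10}\mathrm{EC_{50}}$ — concentrations live on a ratio scale, so
the geometric mean is the natural center and group statistics downstream
run on the log values.

Normalization matters more than it looks: dividing by the
top-concentration amplitude pins that point at exactly 1 while the true
fractional occupancy there is $1/(1+(\mathrm{EC_{50}}/c_\text{top})^h)$.
At $h \approx 1.1$ and a top concentration of $\sim60\times$ EC50 this
biases the fitted EC50 about 3% low. The default follows the
conventional max-normalization; `free_max = TRUE` fits a third,
free-maximum parameter and removes the bias, and the tight synthetic
recovery checks use that variant.

## Imaging quantification

The imaging module works on maximum projections of labeled z-stacks
(`max_project()`), with user-supplied ROIs — there is deliberately no
automatic cell segmentation or dendrite tracing.

* **Surface expression** (`surface_ratio()`): background-subtracted mean
  surface intensity over background-subtracted mean intracellular
  intensity inside the ROI. Background is the median of a user-supplied
  background ROI, falling back to the intensity-histogram mode. A
  non-positive denominator flags the cell rather than erroring.
* **Colorimetric assay** (`colorimetric_ratio()`): replicate absorbances
  are averaged *before* any arithmetic, then intracellular = total −
  surface after background subtraction. Averaging first is not
  equivalent to averaging per-replicate ratios and matches how plate
  replicates are treated.
* **Colocalization** (`adaptive_threshold()`, `percent_overlap()`,
  `count_puncta()`): a pixel is foreground when it exceeds its local
  mean (51-px window by default, clamped to the image) by an offset of
  twice the robust noise SD; local-mean thresholding tracks uneven
  illumination that defeats a global Otsu cut. Overlap is directional —
  the fraction of *surface* pixels lying on PSD-95 — and puncta are
  connected components under 8-connectivity with a 4-px area floor (the
  installed image library labels 4-connected components only, so
  labeling is done in-package on an 8-neighbor pixel graph).

## Group statistics

The pipeline order is fixed: power transform → outlier screen → refit →
ANOVA → post-hoc comparisons.

* The Box-Cox transform is *gated*: it is applied only when the raw data
  fail a Shapiro-Wilk test on the one-way-model residuals or a Levene
  test of variance homogeneity (both at $\alpha = 0.05$ — the screens'
  identity is a package choice; the goal, symmetric homoscedastic data,
  dictates them only up to convention). $\lambda$ is profiled by maximum
  likelihood over $[-3, 3]$; non-positive data are shifted, and the
  shift is recorded so the transform inverts.
* Outliers are observations with externally studentized residuals
  $|r| > 3$ from the group-means model, removed in a single pass — the
  screen is not iterated, and outliers are not re-screened after
  transformation.
* Dunnett many-to-one comparisons versus the wild-type control run on
  the transformed, outlier-free data via multcomp, with unequal group
  sizes supported; `dunnett_critical()` exposes the equicoordinate
  multivariate-$t$ quantile directly (mvtnorm quadrature), and a
  seeded 10,000-replicate null in the test suite confirms the familywise
  error is calibrated at $0.05 \pm 0.01$.
* Duncan's multiple-range procedure is implemented from the textbook
  algorithm (no installed package provides it): ordered means, critical
  range for a span of $p$ means at the protection level
  $(1-\alpha)^{p-1}$, harmonic-mean group size for unequal $n$, and the
  containment rule that a pair inside a non-significant wider range is
  never declared significant. Homogeneous subsets are maximal runs of
  mutually non-significant groups.
* `paired_t()` is the standard two-sided paired test, with zero-variance
  differences flagged instead of erroring.

## Synthetic data: what it does and does not show

The generators produce every substrate the analyses consume, with the
generating truth recorded in a YAML sidecar (`write_ground_truth()`)
and bit-identical regeneration from the recorded seed.

* `gen_trace()`: four-state-model currents through the emulated
  recording chain (10 ms exchange, 2 kHz Bessel, 5 kHz sampling) plus
  additive Gaussian noise scaled to the peak; default peaks sit near
  −500 pA so unit handling is exercised.
* `gen_dr_dataset()`: per-cell Hill amplitudes with multiplicative
  Gaussian noise (CV 0.05 default) on half-log concentration grids
  bracketing the EC50 by at least 1.5 decades.
* `gen_hek_image()`: disk cells with an annular "surface" ring and an
  interior "intracellular" fill whose intensities are set so the planted
  ROI ratio is exact after background subtraction; optional noise and a
  linear illumination gradient.
* `gen_dendrite_image()`: Gaussian puncta along a 20 µm dendrite band; a
  stated fraction of surface puncta is centered exactly on PSD-95
  puncta, off-puncta keep ≥ 4σ clearance from every PSD-95 punctum, and
  same-channel puncta keep ≥ 6σ separation so planted counts stay
  resolvable.

Passing round-trips on these fixtures demonstrates that the analysis
code inverts its own generative assumptions at the stated tolerances.
They do not demonstrate robustness to what the generators omit: open-tip
artifacts, series-resistance and liquid-junction errors, double-exponential
desensitization, receptor rundown, photobleaching, realistic PSFs or
deconvolution residues, or cell-to-cell heterogeneity beyond the modeled
noise. Conclusions about real recordings inherit those caveats.

## Problem sizes and reproducibility

The bundled checks run on deliberately modest problem sizes chosen as
sensible defaults for a deterministic model of this dimension: 5–10 s
simulated applications at 5 kHz (50,000 samples), 10,000-replicate
statistical nulls, and 10-seed imaging batches. Every stochastic step
takes an explicit seed, reruns are bit-identical, and
`scripts/acceptance.R` regenerates the headline numbers from scratch
with the installed package.

## Known limitations

* No agonist binding/unbinding states, no voltage dependence, no
  single-channel (stochastic) simulation; $k_c$ and $k_b$ are fixed by
  convention, not estimated.
* Deactivation (off-) kinetics are out of scope; traces are analyzed up
  to agonist offset.
* One measurement per cell in the statistics stage — no hierarchical or
  mixed models.
* DAPI-based viability gating and cell/dendrite segmentation are manual,
  by supplied ROI masks.
* Trace I/O is delimited text with YAML protocol sidecars; no HDF5 or
  vendor binary formats (no R bindings available in this environment).
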