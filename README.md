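# nmdartools

Quantitative analysis of NMDA-receptor (NMDAR) electrophysiology and
fluorescence imaging, built for studies of GluN2A/GluN2B variants with
truncated C-terminal domains (CTDs) — but useful for any work that
needs macroscopic open-probability estimates from MK-801 block,
desensitization and dose-response fitting, neurosteroid modulation
indices, surface-expression and colocalization quantification, or the
accompanying group statistics.

## What it computes

**Open probability from MK-801 block.** At saturating glutamate the
receptor is modeled by the lumped four-state scheme

```
D <=(k_r/k_d)=> C <=(k_o/k_c)=> O <=(k_b[MK]/k_u)=> B
```

(desensitized, closed, open, blocked). MK-801 enters only open
channels, so the decay of the glutamate response during MK-801
co-application reports channel opening. The estimate is two-step:
(1) a single-exponential fit of control desensitization gives
`k_d = D/tau_d` and `k_r = (1-D)/tau_d`; (2) with those fixed, with
`k_c = 200 s^-1` (conventional anchor) and `k_b = 25 uM^-1 s^-1`, the
opening rate `k_o` is the single free parameter fitted to the
peak-normalized block onset. Then

```
P_o = 100 * k_o / (k_o + k_c)        (percent)
```

**Desensitization.** `D = 100 * (1 - I_SS / I_P)` from a
single-exponential fit of the decay from peak to plateau.

**Steroid modulation.** `E = 100 * (I_S - I_A) / I_A` — positive for
potentiation, negative for inhibition.

**Dose-response.** Per-cell Hill fits
`I = 1 / (1 + (EC50/[agonist])^h)`, pooled on log10 EC50.

**Imaging.** Max projection, background-subtracted
surface-to-intracellular intensity ratios, colorimetric-assay ratios,
adaptive (local-mean) thresholding, percent pixel overlap with PSD-95,
and 8-connected puncta counts on 20 µm dendrite segments.

**Statistics.** Gated Box-Cox power transform, studentized-residual
(|r| > 3) outlier screening, one-way ANOVA with Dunnett many-to-one
comparisons versus wild type, Duncan multiple-range subsets, paired t
tests.

**Synthetic data.** Seeded generators for every substrate (model
currents through an emulated 10 ms-exchange / 2 kHz-Bessel / 5 kHz
recording chain, per-cell Hill datasets, HEK-cell ring/fill images,
two-channel dendrite images with controlled overlap), each with a YAML
ground-truth sidecar and bit-identical regeneration.

## Worked example

Simulate a wild-type-like receptor, then recover its open probability
with the two-step estimate:

```r
library(nmdartools)

p <- kinetic_params(k_d = 0.47, k_r = 0.59,
                    k_o = ko_from_po(19.1, 200), k_c = 200)
ctl <- simulate_current(p, glu_step_protocol(t_app = 5))
mk  <- simulate_current(p, glu_step_protocol(t_app = 10, mk801 = 1))
estimate_po_two_step(ctl, mk)
#> Open-probability fit: k_o = 47.98 1/s -> P_o = 19.35%
#>   fixed: k_d = 0.375, k_r = 0.595, k_c = 200 1/s, k_b = 25 1/(uM s), [MK-801] = 1 uM
#>   RMS residual (normalized current) = 0.000554
```

The generating open probability was 19.1%; the two-step estimate
returns 19.35% — the small bias comes from approximating the four-state
relaxation with a single exponential in step 1 (the step-1 fit reads
`D = 38.7%`, `tau_d = 1.03 s`, hence the slightly perturbed fixed
rates shown). Fixing `k_d`, `k_r` at their true values instead
(`fit_ko(mk, k_d = 0.47, k_r = 0.59)`) recovers `P_o = 19.10%` to
numerical precision.

Dose-response and modulation indices:

```r
cc <- c(0.3, 1, 3, 10, 30, 100)  # uM glutamate
fit_hill(cc, 1 / (1 + (5.0 / cc)^1.09))
#> Hill fit (glutamate): EC50 = 5 uM, h = 1.09

steroid_modulation(1.00, 2.04)$E   # response doubled by the steroid
#> [1] 104
```

A config-driven end-to-end run (`run_pipeline()` /
`read_run_config()`) produces per-genotype summary tables — EC50 and
Hill slope per genotype, and desensitization, rate constants and P_o
with Dunnett significance marks versus the control — and
`write_report()` serializes them losslessly. A thin CLI wrapper lives
in `inst/scripts/nmdartools-cli.R`.

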