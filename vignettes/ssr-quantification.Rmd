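---
title: "Quantifying single-sensillum recordings and odorant coding with sensillaR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying single-sensillum recordings and odorant coding with sensillaR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sensillaR)
```

## The measurement chain

Insect olfactory physiology quantifies odor coding with a small set of
standard statistics, all downstream of one primitive: the extracellularly
recorded action potentials of the receptor neurons housed in a single
antennal sensillum. sensillaR implements that chain for recordings of the
kind made from the six antennal sensillum types of the bed bug *Cimex
lectularius* (three smooth-peg D subtypes Dα/Dβ/Dγ, the grooved peg C, and
the hair-like E1 and E2), but nothing in the code is specific to that
species beyond the archetype preset.

The chain is:

1. **Spike detection** (`detect_spikes`). Voltage traces (96 kHz, 10 s in
   the standard protocol) are thresholded at `threshold_k` robust noise
   units, where the noise scale is the median absolute deviation scaled to
   a Gaussian SD. A spike is logged at each supra-threshold local
   extremum, with a 2 ms suppression window. All events are pooled: the
   convention for multi-neuron sensilla (the C peg houses 4–5 neurons)
   reports whole-sensillum rates, so no spike sorting is attempted.
2. **Firing rates** (`firing_rate`). Spikes in the 500 ms window from
   stimulus onset, minus spikes in the 500 ms immediately before, doubled
   to give spikes/s. Negative values mark inhibition and are kept.
   Windows are half-open `[start, start + w)` so adjacent windows
   partition time.
3. **PSTH** (`compute_psth`). 100 ms bins over the 2 s after onset
   (20 bins). Per-bin counts always sum to the window spike count.
4. **Tuning statistics** (`build_response_matrix`, `band_distribution`,
   `class_bias`, `tuning_curve`, `kurtosis_k`). Replicate rates are
   averaged into an odorant × sensillum matrix; cells under 15 spikes/s
   are flagged non-responders (flagging never alters the stored mean);
   50 spikes/s — one fifth of the strongest response on record, ~248.5
   spikes/s, rounded — is the excitatory criterion. Tuning curves order a
   column strongest-at-center (rank 2 immediately left, rank 3 right, and
   so on outward; ties broken by odorant id), and tuning breadth is the
   corrected sample excess kurtosis
   $$K = \frac{n(n+1)}{(n-1)(n-2)(n-3)}\sum_i\left(\frac{x_i-\bar
   x}{s}\right)^4 - \frac{3(n-1)^2}{(n-2)(n-3)},$$
   the default of the mainstream statistics packages this field uses
   (a Gaussian column gives K ≈ 0; a sensillum with a few strong
   responses over a silent background gives large K). K is computed on
   signed rates by default; a raw (non-excess) variant is exposed.
5. **Odorant space** (`build_space`, `rank_pairs`, `hcluster`,
   `pca_space`). Each odorant is its 6-vector of mean rates; Euclidean
   distance in spikes/s measures discriminability (a 104-odorant panel
   gives 5356 pairs). Hierarchical clustering uses unweighted pair-group
   average linkage — the meaning of "between-group linkage" in SPSS-style
   software: $d(A,B) = \frac{1}{|A||B|}\sum_{a\in A,b\in B} d(a,b)$. PCA
   is run on the 6 × 6 correlation matrix (columns standardized), with
   odorants as observations; each component explains eigenvalue/6 of the
   variance, so all six always total 100%.
6. **Temporal dynamics** (`phasic_tonic_index`, `temporal_cluster`). The
   index is the mean rate in bins 11–20 divided by the peak rate in bins
   1–5; ≥ 0.5 is labelled tonic. The 0.5 cut is our operationalization —
   the literature uses the terms qualitatively. Odorants are clustered on
   their 20-bin count vectors.
7. **Dose-response pharmacology** (`extract_amplitude`,
   `normalize_series`, `fit_hill`, `threshold_dose`). Oocyte currents are
   reduced to peak amplitudes (baseline-median subtracted; lightly
   smoothed only when baseline noise is detected, so noiseless round
   trips stay exact), normalized either to a reference odorant's response
   or so the maximum is 100, and fitted with
   $$R(d) = b + \frac{E_{max} - b}{1 + (EC_{50}/d)^{n_H}}$$
   by least squares on the log10 dose axis.

## The synthetic-data generator

Real traces cannot ship with the package, so every stage is exercised
against a generator whose statistical structure matches what the analyses
assume.

**Spike trains** are inhomogeneous Poisson processes sampled by thinning,
with a hard 2 ms refractory dead time. A hard dead time depresses the
realized rate of a Poisson process ($r_{obs} = \lambda/(1+\lambda\tau)$),
so the thinning hazard is dead-time compensated,
$\lambda(t) = r(t)/(1 - r(t)\tau)$: the realized rate then equals the
target rate function exactly for constant rates and to first order for
slowly varying ones, and attainable rates are capped at $1/\tau$ = 500
spikes/s. The target rate is baseline before onset and baseline +
$A(d)\,k(t)$ after, where $A$ follows a Hill function of dose and the
kernel $k$ is tonic (sustained 1 for the rest of the recording — observed
tonic responses stay high through the full 2 s analysis window) or phasic
($e^{-t/\tau_{decay}}$, default decay 200 ms).

**Voltage traces** are sums of a biphasic template (1.5 ms wide, dominant
lobe of configurable polarity) centered at the nearest sample to each
spike time, plus white Gaussian noise. No 1/f or line-frequency component
is modelled — published recordings give no noise spectrum, and the
detector contract only involves a broadband noise scale.

**The response matrix** comes from an editable archetype preset
(`default_archetypes()`) encoding the qualitative tuning of the six
sensillum types: aldehyde-dominated D sensilla with nonanal the strongest
stimulus on record (~248/213/223 spikes/s on Dα/Dβ/Dγ at the 1:100 v/v
reference dose), an amine-dominated C peg (ammonia/propylamine/butylamine
at 200/195/144) that also responds to 1-methylpiperazine and
thiazolidine, a nearly silent E1, an E2 tuned to long-chain (> C10)
compounds at 20–60 spikes/s, and no carboxylic acid reaching the
excitatory criterion anywhere. Class-level rules assign responder
fractions (e.g. 82% of aldehydes on Dβ) with linearly spaced rates;
odorant-level rules override them. Rates in the rule table are rates *at
the reference dose*; the generator back-computes the Hill asymptote so the
realized rate at 1:100 v/v equals the configured value. Kernels follow the
reported temporal dynamics (propanal, butanal and decanal phasic;
pentanal–nonanal tonic; sulcatone tonic while the aliphatic ketones and
aromatics are phasic).

Two generator settings are assumptions, not reported values, and are
deliberately configurable:

* **Spontaneous rates** are not published per sensillum type. Defaults:
  10 spikes/s for the D types, 15 for C (it pools 4–5 neurons), 5 for
  E1/E2 — ordinary magnitudes for insect ORNs.
* **Dose parameters** of the SSR branch default to EC50 at 1:10^3.5 v/v
  with Hill slope 1, placing the reference dose on the upper shoulder of
  the curve; the dose axis is log10 dilution (−1 … −6), with molar doses
  reserved for the oocyte branch to prevent silent unit mixing.

**Oocyte traces** are piecewise: linear ramp to the Hill-scaled peak
(200 ms), exponential desensitization (default τ = 4 s) over the 10 s
application, exponential washout. Noiseless peaks therefore sit exactly on
the configured Hill curve, which the tests exploit.

What the generator does *not* emulate: spike-amplitude drift and
multi-unit amplitude classes, correlated or line-frequency noise, adapting
baselines, inter-animal variance components beyond Poisson counting noise,
and any quantitative fit to the published measured response table (the
archetypes are qualitative emulations by design). Passing tests therefore
demonstrate that the estimators are correct and calibrated under the
stated stochastic model — not that they are robust to every artifact of
real recordings.

## Numerical choices and degenerate inputs

* Response bands `<50 / [50,100] / (100,150] / (150,200] / >200`: the
  published band labels overlap at the shared endpoints ("≥50, ≤100" is
  followed by "≥100, ≤150"); we assign ties to the lower band so the
  partition is exact, and a cell at exactly 100 spikes/s counts in
  `[50,100]`.
* The tuning-curve prose convention ("strongest at center, weakest at the
  edges") does not fix the left/right alternation; we fix rank 2 to the
  left of center and document the choice; any tie is broken by odorant id
  so shuffled input yields identical output.
* Flat traces make a MAD-relative threshold degenerate; `detect_spikes`
  refuses them with instructions to pass `absolute_threshold`.
* Constant matrix columns make correlation-matrix PCA undefined; the
  error names the offending column. Constant rate vectors make K
  undefined (insufficient-data below n = 4).
* `fit_hill` multi-starts over a grid of candidate log-EC50s (one per
  observed decade, ± 1) and Hill slopes {0.5, 1, 2}, keeps the best
  converged run, flags fits that beat a flat model by less than 1e-6
  relative RSS as unidentifiable, and flags EC50s outside
  [min dose/10, max dose × 10] as extrapolated. The EC50 CI is the delta
  method on log10 EC50; bootstrap is out of scope.
* Half-open windows use a 1e-12 s tolerance so boundary spikes are
  classified consistently under floating-point window arithmetic.

## Problem sizes

The shipped tests and the acceptance script run the full 104 × 6 × 6
study (624 cells, 3744 simulated trains) for matrix-level checks;
Monte-Carlo calibration suites use 100–500 seeded trains per case,
detector operating-point checks use 100 traces at 20 kHz (the 96 kHz /
10 s geometry is verified once), and EC50 recovery uses 200 noisy series.
These sizes keep every distributional check within a few standard errors
of its target while the whole suite runs in a few minutes on one CPU.

## Limitations

The package reproduces an analysis chain, not a biophysical model:
kernels are phenomenological, desensitization is a single exponential,
and no channel kinetics are fitted. EC50s fitted on v/v dilution axes are
in dilution units, not molar. Sensillum subtype identity (Dα vs Dβ vs Dγ)
is metadata supplied by the experimenter, never inferred from the
recording.
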