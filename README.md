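# sensillaR

Quantification of insect single-sensillum recordings (SSR) and the
odorant-coding analyses built on them.

Blood-feeding insects such as the bed bug *Cimex lectularius* locate
their hosts largely by smell. The standard way to characterize that
sense is to screen a panel of host odorants against each type of
antennal olfactory sensillum, recording extracellular spikes from the
neurons inside, and then to ask a fixed set of quantitative questions:
how strong is each response, how narrowly tuned is each sensillum, how
discriminable are the odorants from one another, does a response burst
and adapt (phasic) or persist (tonic), and — for heterologously
expressed odorant receptors — what is the potency (EC50) of each ligand?
sensillaR implements that entire chain as tested, reusable R functions,
together with a seeded synthetic-data generator that emulates the
recordings so the whole pipeline can be exercised and calibrated
offline.

## What it computes

* **Spike detection** from voltage traces: MAD-based adaptive threshold,
  one event per supra-threshold local extremum, 2 ms suppression, no
  unit sorting (whole-sensillum rates).
* **Firing rates**: spikes in the 500 ms stimulation window minus the
  500 ms pre-stimulus window, × 2 → spikes/s (negative = inhibition);
  PSTHs in 100 ms bins over 2 s.
* **Tuning analysis**: odorant × sensillum response matrix with SEMs;
  15 spikes/s non-responder flag; response bands (<50, 50–100, 100–150,
  150–200, ≥200 spikes/s, ties to the lower band); per-class responder
  fractions at the 50 spikes/s excitatory criterion; center-out tuning
  curves and their kurtosis

  K = n(n+1)/((n−1)(n−2)(n−3)) · Σ((xᵢ−x̄)/s)⁴ − 3(n−1)²/((n−2)(n−3))

  (corrected sample excess kurtosis; high K = narrow tuning).
* **Odorant space**: 6-D response vectors, Euclidean distances in
  spikes/s, closest/farthest pair rankings, between-group (UPGMA)
  hierarchical clustering with Newick export, correlation-matrix PCA
  (variance per component = eigenvalue/6), phasic/tonic index and
  temporal clustering of PSTH shapes.
* **Dose-response pharmacology**: peak amplitudes from voltage-clamp
  current traces, normalization (reference odorant or max = 100), Hill
  fits R(d) = b + (Emax − b)/(1 + (EC50/d)^n) with multi-start
  least squares on log dose, delta-method EC50 CIs, and threshold-dose
  inversion.
* **Synthetic data**: dead-time-compensated inhomogeneous-Poisson spike
  trains (thinning, 2 ms refractory), biphasic-template voltage traces,
  a 104-odorant × 6-sensillum archetype preset (aldehyde-tuned D types
  with nonanal strongest, amine-tuned C, long-chain-tuned E2, silent
  carboxylic acids), and desensitizing oocyte current traces — all
  byte-reproducible under a seed.

## Worked example

```r
library(sensillaR)

## simulate the full screen: 104 odorants x 6 sensilla, 6 replicates
m <- gen_response_matrix(seed = 42)
m
#> <response_matrix> 104 odorants x 6 sensilla (624 cells) at 1:100 v/v
#>   replicates: 6-6; non-responders (<15 spikes/s): 562

band_distribution(m)
#>      band count fraction_pct
#> 1     <50   589         94.4
#> 2  50-100    16          2.6
#> 3 100-150    10          1.6
#> 4 150-200     5          0.8
#> 5   >=200     4          0.6

tuning_curve(m, "C")        # the grooved peg: narrowly tuned, amine-driven
#> <tuning_curve> C: 104 odorants, peak 198.7 spikes/s, K = 28.76

sp <- build_space(m)
sp
#> <odor_space> 104 odorants in 6 dimensions; 5356 pairs
rank_pairs(sp, 3, "farthest")[, c("odorant_a", "odorant_b", "distance_1dp")]
#>    odorant_a   odorant_b distance_1dp
#> 1    nonanal propylamine        443.5
#> 2    ammonia     nonanal        438.1
#> 3 butylamine     nonanal        425.2

pca_space(m, 3)
#> <pca_result> 3 components retained; cumulative variance 75.08%

## receptor pharmacology: simulate noisy oocyte currents and refit
doses <- 10^seq(-9, -4)
tr  <- gen_current_trace(5.186e-7, 1, 100, doses, noise_sd = 5, seed = 7)
amp <- sapply(tr, extract_amplitude)
fit_hill(doses, normalize_series(amp, "max_is_100"))
#> <hill_fit> EC50 = 5.286e-07 [3.53e-07, 7.92e-07], Emax = 101.7, n = 0.836
```

Reading the output: 94.4% of odorant-sensillum combinations sit below
the 50 spikes/s excitatory criterion — strong responses are sparse. The
C sensillum's kurtosis of ~29 marks it as the most narrowly tuned
column, and every one of the farthest odorant pairs contains nonanal,
the strongest stimulus in the panel. The Hill refit recovers the
generating EC50 (5.186 × 10⁻⁷ M) within its confidence interval from 5%
measurement noise.

An end-to-end run (`run_pipeline(default_config(seed = 1))`, or the
wrapper `inst/scripts/ssr-pipeline.R all --seed 1 --outdir out/`) writes
every artifact — replicate tables, response matrix, band/bias/tuning
summaries, distance matrix, Newick trees, PCA scores, EC50 table — plus
a machine-readable `summary.json` and a run log carrying the config
hash and seed.

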