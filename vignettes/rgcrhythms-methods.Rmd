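---
title: "Models and methods behind rgcrhythms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rgcrhythms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgcrhythms)
```

## The scientific problem

Retinal output — the spike trains of retinal ganglion cells (RGCs) — varies
over the day, and glial clock genes are one candidate controller of that
variation. The analyses in this package quantify that control from three
kinds of data:

1. **Multielectrode spike trains** from isolated retinae stimulated with
   full-field flashes at several Michelson contrasts, in mesopic and
   photopic luminance regimes, sampled at Zeitgeber times (ZT) 0, 6, 12 and
   18 in two genotypes (control vs. a glial conditional knockout).
2. **Clock-gene qPCR time series** over the same ZT grid.
3. **Flash electroretinograms (ERG)** with a-wave and b-wave amplitudes.

The package implements the full chain — stimulus bookkeeping, spike-train
primitives, ON/ON–OFF/OFF polarity classification, functional sub-clustering,
daily peak-response statistics, luminance-dependent polarity maintenance,
cosinor rhythm fits, and ERG feature extraction — plus a synthetic-data
generator with known ground truth that stands in for recordings that are not
publicly deposited.

## Stimulus model

Full-field flashes alternate 1 s white / 1 s black around an isoluminant
mean gray, 20 trials per contrast, preceded by 5 min of spontaneous-activity
gray and a 60 s gray baseline per block. Contrast is Michelson contrast on
the 0–100 scale,

$$\mathrm{CT} = 100\,\frac{L_{max}-L_{min}}{L_{max}+L_{min}},$$

and flash pairs are symmetric around the gray: $(g(1+\mathrm{CT}/100),\,
g(1-\mathrm{CT}/100))$. The identity `michelson_contrast(contrast_pair(g, ct))
== ct` is exact to $10^{-12}$ and tested. Time is in seconds from protocol
start; all event windows are half-open. Because the presentation order of
contrast blocks is not fixed by the experimental description, blocks default
to ascending CT order and the order is recorded in the protocol object. The
luminance regime (mesopic 0.092 cd/m², photopic 9.20 cd/m²) is carried as
metadata; contrast arithmetic is regime-independent.

## Spike-train primitives

Spikes are epoched into 2 s cycles with phase 0 at white onset ([0, 1) white,
[1, 2) black). Three derived objects drive everything downstream:

* **PSTH** — pooled spike counts in 10 ms bins divided by
  `n_trials * bin_width`, so the spike-count conservation identity
  $\sum_b r_b \,\Delta t \, n_{trials} = N_{spikes}$ holds exactly.
* **Cumulative cycle distribution** — the empirical CDF of pooled spike
  phases on a fixed 200-point grid (10 ms, matching the PSTH bin; the grid
  resolution is our choice, as the source analysis does not state one).
  Normalizing by total count makes the curve sensitive to *when* a cell
  fires, not how much: duplicating every spike leaves it unchanged exactly,
  and 50% random thinning perturbs it only at the $1/\sqrt{n}$ scale.
  Spikes are pooled across trials before the CDF is built; per-trial CDFs
  are not retained.
* **ISI samples** — successive differences of in-window spike times.

## Polarity classification

Units pass two gates before typing:

1. a spontaneous-rate floor of at least 0.1 spikes/s, evaluated on the 5 min
   spontaneous gray segment (inclusive threshold);
2. a two-sided two-sample Kolmogorov–Smirnov test between ISI samples under
   static gray and under maximum-contrast flashes, keeping units with
   $p \le 0.05$ — cells whose interval statistics do not react to the
   stimulus are discarded with a reason code.

Typing itself is greedy template matching: the unit's cumulative cycle
distribution (CT100 block, separately per luminance regime) is compared
under the sup-norm against a library of eight canonical curves —
ON sustained, ON transient ($\tau$ = 80 ms), ON delayed-sustained,
OFF sustained, OFF transient, and three ON–OFF burst mixtures (50/50, 70/30,
30/70) — and takes the class of the nearest template; ties break by library
order, a single pass, no reassignment. A unit whose best distance strictly
exceeds $\theta = 0.25$ is left unassigned (`NA`). The template curves,
their count and $\theta$ are this package's construction (the original
approach defers to unpublished templates); they are configurable and
serializable to JSON so a run's library is fully reproducible.

Two numerical choices matter and are deliberate:

* **Response latency.** All template kernels start 20 ms after their
  half-cycle onset, matching the conduction/transduction lag of real RGC
  responses. Zero-latency templates systematically push transient ON cells
  toward asymmetric ON–OFF templates, because a shifted fast rise is
  penalized heavily under the sup-norm.
* **Sup-norm distance.** KS-like and scale-free on CDFs; an L2 option
  exists. Under the sup-norm a uniform spiker (diagonal CDF) sits ~0.35 from
  the nearest default template and is correctly rejected at
  $\theta = 0.25$.

## Functional clustering

Within each polarity class, cumulative distributions from *all* sessions —
both genotypes, all ZTs, one luminance regime — are pooled, deliberately, so
cluster definitions cannot encode genotype or time of day. Features are
mean-centered principal components retaining the smallest set explaining at
least 90% of variance (the retained count is data-dependent and logged; the
source does not state its rule). K-means (best of 10 seeded restarts by
within-cluster sum of squares) is run for each candidate $k$ in 2–20, and
the $k$ maximizing the mean silhouette width is selected. Cluster ids are
renumbered by descending size so "cluster 1" is always the most abundant;
the original numbering is arbitrary and not reproduced. Mean silhouettes
below 0.4 flag a low-confidence selection: well-separated synthetic
structure scores above 0.5, while an unstructured isotropic cloud scores
below 0.4.

Cluster composition is compared between genotypes on per-retina proportions
(each retina contributes one proportion vector per polarity class), with a
two-sample t-test per cluster and Holm–Šídák correction across the clusters
of that class.

## Daily peak statistics

Peak response is the maximum 10 ms PSTH bin in the preferred half-cycle —
white for ON, black for OFF; ON–OFF cells are excluded from peak analysis
(but retained for maintenance percentages). The analysis grid is the four
most abundant ON and OFF clusters × 4 ZTs × 4 CTs × 2 genotypes. Genotype
differences use two-sided two-sample KS tests at cell level (exact
small-sample p where the test provides it); day-time variation within a
genotype uses one-way ANOVA over ZT with Tukey–Kramer honest pairwise
comparisons (unequal group sizes supported). Scatter summaries normalize
cluster-mean peaks, per ZT, by the maximum *control* cluster-mean over the
contrasts at that ZT; a documented variant normalizes by the day-wide
control maximum instead (two descriptions of this denominator circulate;
the per-ZT one is the default here and the other is a config switch).

Luminance-dependent **polarity maintenance** joins per-unit labels from
mesopic and photopic recordings of the same retina: a unit keeping its label
is *maintained*, a unit changing it *switched*, and units without a template
match in either regime fall into an `NA` group that is counted but excluded
from the percentage denominator. Control vs. knockout maintenance is
compared by a two-sided Fisher exact test on pooled cell counts.

## Cosinor rhythm analysis

Relative expression uses the $\Delta\Delta C_t$ method against a
housekeeping gene, referenced to the mean control-ZT0 $\Delta C_t$ of each
gene (fold change $2^{-\Delta\Delta C_t}$). Rhythms are fit with a
fixed-period cosinor,

$$y = M + A\cos\!\big(2\pi (t - \phi)/24\big),$$

linearized as $y \sim \cos(\omega t) + \sin(\omega t)$ so the fit is
ordinary least squares: $A = \sqrt{\beta^2+\gamma^2} \ge 0$ by construction
and the acrophase $\phi$ is reported modulo 24 h. The period is fixed at
24 h; free-period fitting is out of scope. The cosine is compared to a
horizontal line with the extra-sum-of-squares F test
($F = \frac{(RSS_{flat}-RSS_{cos})/2}{RSS_{cos}/(n-3)}$, $p$ from
$F_{2,n-3}$), and model selection takes cosine when that test has
$p<0.05$, otherwise a line when the slope t-test does, otherwise flat. Note
that at the 4-ZT sampling design a monotone trend aliases partly onto the
cosine basis, so a strong linear drift can legitimately select "cosine";
this is a property of the design, not a defect of the rule. Residual
normality uses the D'Agostino–Pearson $K^2$ omnibus test (implemented
in-package from the standard skewness and kurtosis transforms and verified
against an independent reference implementation), skipped below 8 residuals.
Genotype effects at each ZT use per-ZT two-sample t-tests with Holm–Šídák
correction over the four ZTs within each gene. Replicates enter the fit as
individual observations (animals); the ZT24 point shown in circadian figures
is a display duplication of ZT0 and is never double-counted.

Noiseless cosine inputs are recovered to $10^{-9}$ at any phase, and a
time-shift of the input shifts the fitted acrophase equivariantly (mod 24) —
both are tested exactly.

## ERG feature extraction

Traces span 50 ms pre-trial baseline plus 450 ms of response. Replicates are
averaged pointwise. The a-wave amplitude is baseline minus the voltage
minimum within 0–100 ms (provided it is below baseline; otherwise 0 with a
flag) and the b-wave amplitude runs from the a-trough to the maximum within
0–300 ms. The window minimum is used rather than the literal first local
dip because it is robust on noisy averages and coincides with the first
negative deflection for normal ERG morphology; both search windows are
standard murine ERG timing and configurable, as the source does not state
them. Photopic traces without a measurable a-wave fall back to a
baseline-referenced b-wave and are flagged. An optional few-ms moving
average (`smooth_ms`, default off) stabilizes extremum picking against
residual noise and oscillatory potentials; no other filtering is applied.
Group comparisons gate on Shapiro–Wilk normality of both arms: Student's
t-test when both pass, the two-sample KS test otherwise, and the branch
taken is reported.

Both amplitudes are invariant to constant voltage offsets, and extraction on
noiseless synthetic waveforms returns the generator parameters exactly —
the synthetic waveform descends smoothly to the a-trough and rises to the
b-peak without returning to baseline in between, so trough-to-peak equals
the nominal b amplitude for any a/b combination.

## The synthetic-data generator

The generator defines the study conditions under which every recovery and
calibration claim is tested:

* **Spiking**: inhomogeneous Poisson, rate
  $r(t) = r_0 + g(\mathrm{genotype},\mathrm{ZT})\cdot G \cdot k(t) \cdot
  \mathrm{CT}/(\mathrm{CT}+30)$, sampled by thinning. Kernels $k$ are
  sustained (flat over the preferred half) or transient (exponential,
  $\tau$ = 80 ms), with a 20 ms latency; the contrast response is
  Naka–Rushton-shaped with semisaturation CT 30. Defaults: spontaneous rate
  1 spike/s, evoked peak gains 60 (sustained) and 120 (transient) spikes/s —
  textbook values for well-driven murine RGC full-field responses. An
  optional 1.5 ms absolute refractory period exists for ISI realism and is
  off by default (no tested property needs it).
* **Population**: 50 ON / 20 OFF / 40 ON–OFF units per retina for
  end-to-end runs (a ~1/5 scale model of the ~241/97/194 average real
  yield), 300 per class for classifier-recovery measurements, over the
  2 genotypes × 4 ZTs × 2 regimes grid.
* **Injected effects**: multiplicative peak-gain factors per genotype × ZT
  (default: control elevated ×1.2 at ZT0 and ZT12, knockout ×1.5 at ZT18)
  and polarity-maintenance probabilities per class × genotype × ZT (OFF
  maintenance reduced in the knockout, most strongly at ZT0). These encode
  the qualitative study findings purely as recoverable ground truth.
* **Expression**: cosine + Gaussian noise at ZT 0/6/12/18, with gene
  defaults peaking at ZT6 (Bmal1, Dbp) or ZT12 (Per1, Cry1), noise
  $\sigma = 0.2 \times$ amplitude, and a −4 h knockout acrophase shift for
  all genes except Dbp.
* **ERG**: the piecewise-cosine waveform above, with additive white noise.

All generators are pure functions of (parameters, seed); identical seeds
give byte-identical outputs.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real recordings: spike-sorting errors and unit
contamination, refractoriness and bursting (by default), adaptation within
and across trials, correlated noise across cells, receptive-field and
spatial structure, eye-to-eye variability, qPCR efficiency differences, and
ERG oscillatory potentials. Recovery rates measured here are upper bounds
on what identical methods would achieve on real data.

## Problem sizes and determinism

Tests and the acceptance script run the study conditions at sizes chosen to
exercise the claims without waste: 900-unit populations for classifier
recovery, 240 units for clustering recovery, 500 seeds for cosinor phase
recovery, 200 seeds for thinning stability and effect detection, and 1000–
2000 replicates for type-I calibration of the KS gate, the ZT ANOVA and the
genotype KS test. Every stochastic step takes an explicit seed; k-means uses
seeded restarts with deterministic sub-seeds, so fixed seeds give
byte-identical label files. Degenerate inputs follow documented rules:
zero-spike units are rejected before CDF construction, identical curves
yield a single zero PCA component, empty k-means clusters trigger a logged
reseed, degenerate Fisher margins return p = 1 with a warning, and constant
residual vectors skip the normality test with a flag.

## Known limitations

* Template shapes and $\theta$ are constructions of this package; real
  template sets derived from labelled data would differ, and the NA rate
  depends directly on $\theta$.
* The sup-norm on CDFs under-weights sustained-vs-transient differences
  late in the half-cycle relative to onset dynamics; the L2 option trades
  this off differently.
* Silhouette-selected k on real data is expected to be larger (10–12 per
  class) and less crisp than on the well-separated synthetic kernels; the
  low-confidence flag exists for exactly that regime.
* The cosine/linear/flat selection is ambiguous at 4 samples per period for
  monotone trends (aliasing, discussed above).
* Exact KS p-values are used only where the underlying test provides them
  (small samples, no ties); elsewhere the asymptotic approximation applies
  and is slightly conservative.
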