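# rgcrhythms

Analysis of daily (circadian) changes in retinal function from three kinds of
electrophysiology and expression data, for retina and chronobiology labs
working with high-density multielectrode array (MEA) recordings:

* **Retinal ganglion cell (RGC) light responses.** Sorted spike trains from
  retinae stimulated with full-field flashes (1 s white / 1 s black, 20
  trials) at Michelson contrasts CT25–CT100 around an isoluminant gray
  (CT = 100·(L<sub>max</sub>−L<sub>min</sub>)/(L<sub>max</sub>+L<sub>min</sub>)),
  in mesopic and photopic regimes, at Zeitgeber times ZT 0/6/12/18, in two
  genotypes. The pipeline filters units (≥ 0.1 spikes/s spontaneous rate;
  Kolmogorov–Smirnov responsiveness test on inter-spike intervals),
  classifies ON / ON–OFF / OFF polarity by greedy template matching on
  normalized cumulative spike-phase distributions, splits each class into
  functional clusters by PCA + silhouette-selected k-means, and computes
  peak firing-rate statistics (per-stratum KS tests, one-way ANOVA with
  Tukey–Kramer across ZTs, control-normalized scatter) and
  luminance-dependent polarity maintenance with Fisher's exact test.
* **Clock-gene expression.** ΔΔCt relative quantification and fixed-period
  cosinor fits, y = M + A·cos(2π(t−φ)/24), with extra-sum-of-squares F
  model selection (cosine / linear / flat), D'Agostino–Pearson K² residual
  normality, and per-ZT genotype t-tests with Holm–Šídák correction.
* **Flash ERG.** a-wave (baseline to first negative trough) and b-wave
  (trough to peak) amplitude extraction, replicate averaging, and a
  Shapiro–Wilk-gated t-test / KS comparison between groups.

A first-class synthetic-data generator (`simulate_session()`,
`simulate_expression()`, `simulate_erg()`, `simulate_cohort()`) reproduces
the statistical structure of each data type with known ground truth, so
every recovery and calibration claim in the test suite is checked against
injected effects. See the methods vignette
(`vignettes/rgcrhythms-methods.Rmd`) for the models, parameter choices and
limitations.

## Worked example

Simulate one retina and classify its units:

```r
library(rgcrhythms)

sess <- simulate_session(counts = c(ON = 100, OFF = 40, ONOFF = 80), seed = 42)
sess
#> <rgc_session> Ctrl, ZT0, mesopic regime, 220 units, 535090 spikes (sim1)

calls <- classify_session(sess)
table(calls$label, useNA = "ifany")
#>
#>   OFF    ON ONOFF
#>    40    94    86

# agreement with the generator's ground truth
truth <- session_truth(sess)
mean(calls$label == truth$cell_class[match(calls$unit_id, truth$unit_id)])
#> [1] 0.9727273
```

220 units were simulated, all passed the rate and responsiveness filters,
and 97.3% received their true polarity label; the handful of errors are
transient ON cells whose maintained baseline firing makes them resemble an
asymmetric ON–OFF template. Fitting a rhythm to simulated clock-gene
expression:

```r
expr <- simulate_expression(n_per_zt = 6, seed = 1)
bmal <- dplyr::filter(expr, gene == "Bmal1", genotype == "Ctrl")
fit <- cosinor_fit(bmal$zt, bmal$value)
fit
#> <cosinor_fit> n = 24, baseline 0.9727, amplitude 0.5163, acrophase ZT6.03 (period 24 h)
#>   model: cosine (F = 188, p vs flat = 4.01e-14)
```

The generator's truth for Bmal1 is baseline 1, amplitude 0.5, acrophase
ZT6; at the default noise level (σ = 0.2 × amplitude) the fit recovers the
acrophase within two minutes of clock time. The ERG worked example uses the
group means reported for photopic b-waves (control 111.1 μV vs knockout
70.91 μV):

```r
percent_reduction(111.1, 70.91)
#> [1] 36.17462
```

an approximately 36% b-wave reduction.

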