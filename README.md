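# pjresbin

Correlation-based binning of pJRES ¹H NMR spectra.

## What problem this solves

¹H NMR metabolic profiling of biofluids produces spectra with tens of
thousands of chemical-shift variables that correspond to at most a few
hundred metabolites. Before any statistics, adjacent variables belonging to
one resonance should be collapsed into a single feature ("binning" or
"bucketing"). For 1D projections of J-resolved spectra (pJRES) this is
harder than it looks: the electronic noise is locally correlated, so methods
that segment the axis by local covariance structure — including statistical
recoupling of variables (SRV) — happily produce clusters of pure noise, and
fixed-width bins mix overlapping peaks and noise alike.

`pjresbin` is for NMR metabonomics practitioners who need a feature matrix
per metabolite resonance rather than per spectral point. It implements:

* **JBA-style correlation-guided binning** (`runJBA()`): slide a window of
  `st` adjacent variables along the axis and compute the mean of all
  pairwise correlations in each window, giving a "pseudo-NMR spectrum"
  r̄(δ); take local maxima with r̄ ≥ *ct* as seeds; grow each seed while the
  cluster's average correlation stays ≥ *ct* and each new variable
  correlates at least as strongly toward the cluster as away from it
  (r(vᵢ, vᵢ₊₁) ≥ r(vᵢ, vᵢ₋₁) on the upfield side, mirrored downfield);
  aggregate member intensities (sum/mean/median/max); merge adjacent
  clusters whose intensities correlate above 0.90 (split-peak repair).
* **Data-driven threshold selection** (`selectCt()`): *ct* is placed where
  the empirical CDF of window correlations from a noise-dominated region
  (e.g. δ 9.72–9.99) reaches 1, so no noise window passes — contrasted with
  a metabolite-rich region (e.g. δ 3.50–3.97) as a sensitivity check.
* **Comparators**: SRV (`runSRV()`: cluster edges at local minima of the
  covariance/correlation landscape cov/cor = sᵢ·sᵢ₊₁, minimum cluster size
  `minsize`, Pearson > 0.90 superclusters) and equidistant binning
  (`standardBin()`).
* **Evaluation battery** (`crossCorrelate()`, `compareMethodsPaired()`,
  `pcaDiagnostics()`): Spearman cross-correlation of binned features with
  external metabolite concentrations (e.g. GC-MS), paired signed-rank
  comparison of methods, and PCA variance/QC diagnostics with a Hotelling
  ellipse.
* **A synthetic pJRES generator with ground truth**
  (`generateSpectra()`, `plasmaLikeScenario()`): Lorentzian peaks driven by
  log-normal latent concentrations, AR(1)-correlated noise with an
  undulating floor, optional integer-grid misalignment, and exact per-peak
  supports — so every claim above is testable without any external data.

The methods vignette (`vignettes/pjresbin-methods.Rmd`) documents the model,
all numerical conventions, and the design of the synthetic scenario.

## Worked example

```r
library(pjresbin)

spec <- plasmaLikeScenario(seed = 101)   # canned synthetic plasma scenario
sim  <- generateSpectra(spec)
s    <- sim$spectra
s
#> SpectraSet: 100 samples x 12001 spectral variables
#>   ppm range: 0.4000 .. 10.0000 (median step 0.0008)

## choose the correlation threshold from the designated regions
sel <- selectCt(regionWindowCorrs(s, spec$regions$noise,  st = 4),
                regionWindowCorrs(s, spec$regions$signal, st = 4))
sel
#> CtSelection: ct = 0.512 (noise quantile 1)
#>   noise windows: 335 (max 0.512); signal windows: 585 (5.8% >= ct)

bins <- runJBA(s, jbaParams(st = 4, ct = selectedCt(sel)))
bins
#> BinnedSet (JBA): 42 clusters x 100 samples
#>   cluster sizes: 4 .. 11 variables (median 6.5)
#>   ppm coverage: 0.8784 .. 9.0248

peakRecovery(bins, sim$truth)$fraction
#> [1] 0.9285714

head(as.data.frame(clusterInfo(bins)[, c(1, 2, 3, 4, 5, 8)]), 5)
#>           start_idx end_idx n_variables ppm_start ppm_end     r_bar
#> cluster_1       599     604           6    0.8784  0.8824 0.6406683
#> cluster_2       672     679           8    0.9368  0.9424 0.7372246
#> cluster_3       680     687           8    0.9432  0.9488 0.5695379
#> cluster_4       735     744          10    0.9872  0.9944 0.5568563
#> cluster_5       798     806           9    1.0376  1.0440 0.5519138
```

The threshold (0.512) sits at the top of the noise-window correlation
distribution: every window inside δ 9.72–9.99 falls below it, so the 42
clusters all lie in signal territory — 26 of the 28 planted peaks are
recovered with boundary error ≤ 2 variables (93%), the exceptions being the
two deliberately faint tail peaks whose 1%-of-apex supports are below the
noise floor. `writeBins()` exports the cluster table (one row per cluster,
one aggregated intensity column per sample).

A command-line wrapper with subcommands `simulate`, `select-ct`, `bin` and
`evaluate` is installed at `inst/scripts/pjresbin`; every run writes a JSON
manifest (parameters, input checksums, package version) next to its output.

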