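# tracequant

Quantification toolkit for neural tract-tracing studies: semi-automated
fluorescent tracer injection-site quantification across serial sections,
per-cell intensity-correlation (ICQ) colocalization analysis, and
pharmacological decomposition of inhibitory postsynaptic currents (IPSCs)
into glycinergic and GABAergic fractions.

It is written for labs that inject retro-/anterograde tracers into a
brainstem nucleus (e.g. the MNTB), trace the nucleus outline per section,
and need objective, reproducible answers to three questions:

1. **How much of the nucleus did the injection fill, and where was its
   epicenter?** Per section, in the tracer (TRITC) channel, the labeling
   threshold is

   `threshold = mean + 2·SD`

   of the pooled pixel set (nucleus ROI plus three background sample boxes,
   each 1% of the image area), with the upper bound
   `threshold = 255 − 2·SD` when the first rule exceeds the 8-bit maximum.
   Pixels strictly above threshold inside the ROI are labeled; a
   dynamically expanding box (initial area 1.25 × ROI area, each 1-px-wide
   side expanding while ≥ 10% of its pixels exceed threshold) estimates
   spillover outside the nucleus. Areas become volumes via
   pixel size² × section thickness, and the headline number is the injected
   volume percentage, with a ≥ 70% antero-posterior coverage rule.

2. **Does an immunolabel colocalize with a genetic marker per cell, and
   does that differ between groups?** Li's intensity correlation analysis:
   per pixel, PDM = (Aᵢ − Ā)(Bᵢ − B̄), and

   `ICQ = #{PDM > 0} / #{PDM ≠ 0} − 0.5 ∈ [−0.5, +0.5]`,

   plus the normalized colocalization color map (PDM / max-deviation
   product) for hot spots, and a two-sided Mann-Whitney rank-sum test
   between groups of per-cell ICQ values.

3. **What fraction of evoked inhibition is GABAergic vs glycinergic?**
   From amplitudes under blockers:
   `f_GABA = (A_strychnine − A_both) / (A_total − A_both)`,
   `f_glycine = 1 − f_GABA`, with Welch's t-test between age groups.

Since the raw data of such a study cannot ship with a package, every stage
comes with a seedable synthetic-data generator (`generateInjectionSeries`,
`generateColocCells`, `generateIpscExperiment`) that emits a ground-truth
manifest, so the full pipeline is testable closed-loop. See the methods
vignette (`vignettes/tracequant-methods.Rmd`) for models, conventions and
design decisions.

## Worked example

```r
library(tracequant)

## synthetic 10-section series: true injected volume fraction 14%
g <- generateInjectionSeries(seed = 42)
quants <- lapply(seq_along(g$sections), function(i)
  quantifySection(g$sections[[i]], g$rois[[i]]))
summarizeInjection(quants, totalApExtentSections = 12)
#> InjectionSummary: 13.99% of nucleus volume injected
#>   epicenter section 6 (26.0% of section area)
#>   antero-posterior coverage 83% (meets the 70% rule)
#>   spillover volume 0 um^3

quants[[5]]
#> SectionQuant #5: ROI 2621 px, labeled 682 (26.0%), spillover 0 px
#> ThresholdSpec: mean 46.485, sd 63.781 -> threshold 174.048
```

The estimate (13.99%) recovers the generating truth (13.99% realized after
blob-area rounding); the per-section object retains the threshold, the
background boxes and the final spillover box for audit, and
`writeQuantCsv()` exports the documented per-section table.

```r
## per-cell ICQ, 60 cells per group, generating correlation 0.5 vs 0.0
young <- generateColocCells(60, rho = 0.5, group = "p14",  seed = 1)
adult <- generateColocCells(60, rho = 0.0, group = "p55+", seed = 2)
icqY <- icqTable(young$stack, young$cells)
head(icqY, 3)
#>    cell_id group n_pixels        icq
#> 1 cell_001   p14      111 0.14864865
#> 2 cell_002   p14      109 0.08715596
#> 3 cell_003   p14      112 0.15178571
compareIcqGroups(icqY$icq, icqTable(adult$stack, adult$cells)$icq)
#> GroupComparison (Mann-Whitney rank-sum, normal approximation with continuity correction):
#>   W = 3583, p = 8.248e-21; n = 60 vs 60; medians 0.152 vs 0.004505

## IPSC fractions, groups of 5 and 4 cells, generating GABA fractions 0.24 / 0.06
summarizeIpscGroups(generateIpscExperiment(seed = 3)$records)
#> FractionSummary (Welch t-test): t = 33.466, p = 2.886e-06
#>  group n  gaba_mean     gaba_sd glycine_mean
#>    p14 5 0.24232667 0.012117867    0.7576733
#>   p55+ 4 0.05862415 0.001746749    0.9413758
```

A positive mean ICQ (~0.15 at generating correlation 0.5 — close to the
bivariate-normal prediction asin(0.5)/π ≈ 0.17) separates cleanly from the
uncorrelated group; the recovered GABA fractions (0.242, 0.059) match the
generating values within noise.

A thin command-line wrapper for the injection workflow is installed at
`inst/scripts/quantify-injection.R` (TIFF + ROI-JSON directories in,
per-section CSV + summary JSON out).

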