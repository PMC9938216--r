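---
title: "Methods: from membrane-proteome Z-ratios to network synchrony"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from membrane-proteome Z-ratios to network synchrony}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

membranet reimplements, as one tested pipeline, the analysis chain used
to characterize a copy-number-variant (CNV) mouse model of
neuropsychiatric disease: quantitative membrane proteomics by stable
isotope labeling in mammals (SILAM), disease gene-set profiling,
protein-protein interaction (PPI) subnetwork and hub analysis, calcium
and glutamate imaging analytics, and seizure/behavior statistics. Every
stage is driven by a synthetic-data generator that plants known ground
truth, so the pipeline's operating characteristics (sensitivity,
specificity, null calibration) are measurable rather than assumed.

## Quantification: replicate Z-scores and Z-ratios

The measured unit is a light/heavy (^14^N/^15^N) intensity ratio per
protein per biological replicate, with a peptide-fit quality $r^2$
attached. Post-processing runs in a fixed order, chosen so that
outliers can never contaminate the standardization statistics:

1. **Quality filter** — keep entries with $r^2 > 0.5$ (strictly).
2. **Aggregation** — peptide-level duplicates collapse to the protein
   level by the median (robust after the next step removes the worst
   values anyway).
3. **Grubbs filter** — per protein across its replicate values,
   iteratively remove the single most extreme value while the
   two-sided Grubbs statistic $G = \max|x_i - \bar x| / s$ exceeds its
   critical value at $\alpha = 0.01$:
   $G_{crit} = \frac{n-1}{\sqrt n}\sqrt{\frac{t^2_{\alpha/(2n),\,n-2}}{n - 2 + t^2_{\alpha/(2n),\,n-2}}}.$
   Testing requires $n \ge 3$; zero-variance input leaves $G$
   undefined and removes nothing.
4. **Coverage filter** — keep proteins quantified in at least three
   replicates of each genotype.
5. **Z-scores** (per replicate $i$, across the proteins quantified in
   it): $Z_{(P,i)} = (P_i - \mathrm{Mean}_i)/\mathrm{SD}_i$.
6. **Z-ratios**: with $\bar Z_{p,dup}$ and $\bar Z_{p,wt}$ the
   genotype-averaged Z-scores of protein $p$ and
   $Z_{diff}(p) = \bar Z_{p,dup} - \bar Z_{p,wt}$,
   $\mathrm{Zratio}_p = Z_{diff}(p) \,/\, \mathrm{SD}[Z_{diff}(p_1 \ldots p_n)].$
7. **Calls** — up if $\mathrm{Zratio} > 1.96$, down if $< -1.96$, both
   strict.

Two conventions are deliberate and configurable. Ratios are
log2-transformed before Z-scoring (`log_transform = TRUE`): isotope
ratio noise is multiplicative, and the symmetric log scale keeps a
2-fold decrease as informative as a 2-fold increase. The replicate SD
uses the sample ($n-1$) convention, the common default of statistical
software. Because the Z-ratio denominator is the *empirical* SD of the
per-protein Z-differences, the null distribution of Z-ratios is
approximately standard normal whatever the replicate noise level; with
no planted effect roughly 5% of proteins exceed $\pm 1.96$, which the
test suite asserts as a fraction between 1% and 10% across seeds.

Degenerate inputs fail loudly: a replicate with zero variance (or fewer
than two proteins) stops `zscore_replicates()` naming the replicate,
and an all-equal Z-difference vector (SD exactly 0, possible only in
constructed data) stops `zratio()` rather than yielding infinities.

## Gene-set profiling and interactome calling

Over-representation uses the hypergeometric distribution with the
*detected membrane proteome* as the background universe: genes absent
from the background are excluded from every set before testing, so
membrane-enrichment bias cannot masquerade as disease association. For
an overlap of $k$ between a query of $n$ genes and a set of $K$ genes
in a universe of $N$:

- $p = P(X \ge k)$ (upper tail, observed value included); the
  two-sided variant doubles the smaller tail, capped at 1;
- fold $= k / (nK/N)$; percent enrichment $= (\mathrm{fold}-1) \times 100$.

Profiles over a collection apply Benjamini-Hochberg correction within
each direction's family (up and down are reported as separate panels).
At the published margins — 150 of 208 bait interactors inside 1683
dysregulated proteins of a 4447-protein background — the fold is 1.91,
printed as 1.9.

Interactome calling from bait-vs-IgG spectral counts requires mean
bait count $\ge 2\times$ mean IgG count *and* a one-tailed Welch
t-test $p < 0.1$. Proteins absent from the IgG control (mean 0,
positive bait mean) pass the fold criterion by convention and are
tagged `not_in_control`; Welch is used because equal variances cannot
be assumed for counts this small.

## Subnetworks and hub statistics

Subnetworks are induced subgraphs of a physical-interaction edge list
on a seed protein set; gene symbols are uppercased for matching so
mouse protein identifiers meet human gene lists. Association-weighted
network expansion belongs to an external service and is *not*
reimplemented; a plain top-degree-neighbour expansion (`expansion_k`)
is offered instead. Bait (IAP-MS) edges merge with source-tag
provenance (`database`, `iap`, or both on a deduplicated edge).

Hub statistics are degree $D$ and exact shortest-path betweenness
$C_B$, normalized by $(n-1)(n-2)/2$ so a star centre scores 1 and the
published scale ($C_B$ values below 1) is matched. Unreachable pairs
contribute zero; ranking ties break lexicographically so reports are
reproducible. The suite checks `centrality()` against an exhaustive
all-pairs path-enumeration oracle on 100 random graphs of up to 8
nodes.

Hub *prediction* overlays each candidate gene's co-expression set on
the subnetwork with the same hypergeometric machinery and attaches
constraint (pLI), disease flags and proteome Z-ratio annotations
verbatim — no composite score is computed, matching how the evidence
lines are weighed qualitatively.

## Trace analytics and the co-activation null

Traces are normalized to $\Delta F/F_0$ with a running-median baseline
(window `baseline_window_s`, default 30 s — long relative to the
transients, short relative to drift). Slice recordings are smoothed
first with a 5-point binomial FIR kernel; the original smoothing
filter's wavelet family is unstated, so a fixed, documented kernel was
chosen for reproducibility.

Peaks are local maxima filtered by *topographic prominence* (height
above the higher of the two flanking saddles) at the kind-specific
threshold: 0.15 for cultures, 0.20 for slices, 0.01 for the glutamate
sensor. Prominence, not raw height, is what rejects noise ripples
riding on a decay shoulder. Amplitude is the $\Delta F/F_0$ value at
the peak; half-width is the width at half amplitude with sub-frame
linear interpolation. On noise-free templates the detector recovers
amplitude to well under 1%; edge-adjacent transients (within ~10 s of
a recording boundary) are excluded from fidelity measurements because
the running median is biased there.

The minimal co-active cell count that constitutes a network event is
set by a Monte-Carlo permutation null: each ROI's peak frames are
redistributed uniformly at random (count-preserving), 1000 times, and
the threshold is the ceiling of the 99.9th percentile of the pooled
frame-wise co-active counts. Redistribution is the weakest-assumption
null; a circular-shift variant (which preserves within-train structure)
is available via `scheme = "circular"`. Pooling across all frames and
permutations follows the "percentile of the sum of events over the
simulations" reading; a per-permutation-maximum pooling would give a
family-wise rather than per-frame guarantee and is intentionally not
the default. On independent rasters (100 ROIs, 1200 frames, peak rate
0.01/frame) the permutation threshold matches the analytic
Binomial(100, 0.01) 99.9% quantile within one count, and the fraction
of null frames at or above it stays at the permille level.

Network events are contiguous runs of frames at or above threshold, no
gap bridging (the simplest rule consistent with counting co-active
cells per event); event size is the number of *distinct* ROIs peaking
inside the run. Synchrony is also summarized as the mean Pearson R of
all ROI pairs on the continuous traces (constant traces are excluded
and flagged; raster-based correlation was considered and rejected
because the wording of the source method points at the signals
themselves) and as the mean nearest-event delay per pair within
$\pm 2.1$ s. Population events split into high and low synchrony at
0.2 $\Delta F/F_0$, strict ">" for high, so a peak exactly at the cut
is low — an explicit boundary convention.

Evoked responses normalize to the mean of the first 50 frames, then
report the post-stimulus maximum, the trapezoidal AUC, and the decay
half-life $T_{1/2} = \ln 2 / k$ from a one-phase exponential fit. The
fit is `nls` seeded by a log-linear regression of the decay; perfectly
noise-free decays make the nls residual exactly zero and its iteration
fail, in which case the log-linear estimate (exact in that situation)
is used. Non-convergent fits return `NA` with a flag and leave
amplitude and AUC intact.

## Seizure and behavior statistics

Fisher's exact test is computed directly: all tables with the observed
margins are enumerated via the hypergeometric mass, and the two-sided p
sums every table whose probability does not exceed the observed one (a
$1+10^{-7}$ relative tolerance absorbs floating-point ties). This
"sum of small p" rule is the common package default and reproduces the
published GTCS incidence p of 0.0324 from the reconstructed 14/17 vs
7/16 table. GTCS onset is analyzed with Kaplan-Meier curves and the
log-rank test; animals without a GTCS are censored at the 7200-s
observation end, never dropped. Racine severity scores (1-7, 7 =
death) are ordinal: medians/IQRs plus a rank test. For total n at or
below 12 the Mann-Whitney p is computed by exact rank-permutation
enumeration, because the tied scores defeat `wilcox.test`'s exact
path; larger groups delegate to `wilcox.test`. The discrimination
index is $(t_{mouse}-t_{object})/(t_{mouse}+t_{object}) \times 100$,
and the latency-shift summary is the mean over induction trials of the
ratio of genotype mean latencies, expressed as percent change, using
only trials where both genotypes seized.

## What the generator emulates — and what it does not

`syn_config()` defaults encode the study conditions: 1000 proteins in
5+5 biological replicates with a planted 1 log2-unit genotype effect
in 5% up / 5% down of proteins and 0.2 log2 units of replicate noise;
a 4000-gene universe with a 3-fold-enriched planted set (competitor
sets at fold 1, so ranking tests have a null field); a 100-node
preferential-attachment graph whose hub is reinforced with 20 extra
edges; 150 ROIs recorded 10 min at 2 frames/s; WT/DUP cohorts of
16/17 animals at 44%/82% GTCS incidence; and 330 bait/IgG proteins
with 30 true interactors.

Values the source conditions do not pin down were chosen once, on
field-realistic grounds, and are documented here:

- **Between-protein baseline spread** `protein_sd = 1` log2 unit —
  typical inter-protein dispersion of ratio tables.
- **Transient template** — instantaneous rise, exponential decay with
  FWHM equal to `transient_halfwidth_s` (1 s): reproduces the
  reported amplitude/half-width metrics without inventing indicator
  kinetics. Trace noise 0.05 ΔF/F0, i.e. SNR 10 against the default
  0.5-amplitude transient.
- **Network-event rate** `network_rate_hz = 0.05` (one synchronized
  burst per ~20 s, a few per minute, the scale visible in
  disinhibited-culture rasters); per-ROI independent transients at
  `event_rate_hz = 0.01`.
- **Hub planting** — the extra hub edges attach to the node already
  leading the degree distribution of the scale-free base; attaching
  them to a random node would leave the "planted" hub below the
  natural tail and make hub recovery ill-posed.
- **GTCS latency** — Weibull with shape 2 (smooth, increasing hazard;
  no distributional claim is made in the source), truncated to the
  observation window for seizing animals via the inverse CDF.
- **RNG discipline** — each generator draws from a sub-stream at a
  fixed offset from `cfg$seed`, and traces use one sub-stream per ROI,
  so enlarging a recording does not reshuffle earlier ROIs.

The generator emulates *statistical* structure only. It does not
simulate raw spectra or chromatograms, microscopy pixel data or ROI
segmentation, motion artifacts, photobleaching (beyond a slow
sinusoidal drift), bursting temporal structure within a ROI, or
correlated missingness in the quantification table (missingness is
MCAR). Passing recovery tests therefore demonstrates the analysis
chain's correctness and calibration under the stated noise model — not
robustness to every artifact of real recordings.

## Test problem sizes

The suite runs everything at desk scale: oracle equivalences use
universes up to 20 genes, 2x2 tables up to total 12 and graphs up to 8
nodes (where exhaustive enumeration is feasible); recovery and
calibration runs use 300-1000 proteins, 30-100 ROIs and 5-10 minute
recordings over handfuls of seeds. The dataset-level headline numbers
of the original study (659/1024 dysregulated proteins, a ~100-node
epilepsy subnetwork, the bait's $D = 16$ and $C_B = 0.37$, a Z-ratio
of 115.6) require the full MS accessions and external interaction and
co-expression databases; they serve as reference values in
documentation, while the code paths that would produce them are the
ones exercised by these tests.

## Known limitations

- The Grubbs criterion sentence in the source reads inverted relative
  to standard usage ("data with a p value greater than this threshold
  were removed"); standard outlier removal at $\alpha = 0.01$ is
  implemented.
- Whether ratios were log-transformed before Z-scoring in the original
  chain is unstated; both modes are supported, log2 is the default.
- The two reporting conventions in the source's disease-profile figure
  (one-sided vs two-sided hypergeometric p) cannot both be reproduced
  per panel; both are exposed via `alternative`.
- Trace I/O is CSV (wide, one ROI per row, frame rate in a header
  comment); an HDF5 reader/writer is not provided.
- `fisher_2x2` reports the sample odds ratio, not the conditional MLE.
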