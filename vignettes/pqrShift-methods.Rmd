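---
title: "Methods: screening protein quantitative ratios for complex remodeling"
author: "pqrShift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening protein quantitative ratios for complex remodeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the model

Subunits of a stable protein complex are produced and degraded in a
coordinated way, so the *ratio* of two co-complex proteins' abundances — the
protein quantitative ratio (PQR) — is far more stable across samples than
either abundance alone. When a complex is remodeled (a subunit swapped,
sequestered, or released), the PQR of the affected pairs shifts even if the
individual abundances stay within their normal ranges. `pqrShift` screens a
log-scale protein × sample matrix for exactly this signal: pairs of known
stable interactors whose PQR in *test* samples (e.g. an aggressive tumor
subtype) is an outlier relative to a *reference* sample group (e.g. an
indolent subtype or healthy tissue).

For a pair with per-sample log-ratio $x_i$ (a subtraction, since the matrix
is log scale), the reference samples provide a robust location and scale:
the median $\tilde{x}$ and the raw median absolute deviation
$\mathrm{MAD} = \mathrm{median}_i\,|x_i - \tilde{x}|$. Each test sample is
scored with the modified z-score

$$M_i = \frac{0.6745\,(x_i - \tilde{x})}{\mathrm{MAD}},$$

where $0.6745 \approx \Phi^{-1}(0.75)$ converts MAD units into
normal-equivalent standard deviations. Samples with $|M_i| > 3.5$
(a widely used robust-outlier convention; the inequality is strict) are
outliers, and the pair's score is $\sum |M_i|$ over its outlier samples.
Absolute values are summed so that shifts of opposite sign in different
samples reinforce rather than cancel.

**The single most error-prone convention:** the MAD in the denominator is
*unscaled*. The 0.6745 numerator *is* the normal-consistency correction; a
1.4826-scaled MAD would double-correct. The reciprocal constant 1.4826
appears in exactly one other place — the protein-level variability band
below — and the two are never interchangeable.

## Significance: a randomized background and a moment-matched gamma

Scores are calibrated against a null in which pair structure is destroyed
but reference variability is preserved. For each of $n$ random pairs of
analyzed proteins, each slot receives a randomly chosen protein's
*reference* values: a permutation of them across the reference positions
(so the null median/MAD are estimated from the true reference sample) and
draws with replacement for the test positions. Missing values are carried,
preserving each donor's missingness rate. The full scoring path runs on
these pseudo-pairs, and a gamma distribution is fitted to the resulting
scores by matching moments ($\hat\alpha = m^2/v$, $\hat\beta = m/v$).
A pair's p-value is the fitted gamma's upper tail at its score;
Benjamini–Hochberg adjustment is applied across the testable pairs, with
significance at adjusted $p < 0.1$ and an advisory flag for the top 1% of
scores ($\lceil 0.01\,n \rceil$ pairs, ties broken by smaller p then pair
key).

Zero scores legitimately dominate the null and the moment fit tolerates
them; only if more than 95% of background scores are exactly zero does the
model fall back to a rank-based empirical tail with a pseudocount, and the
run log records the fallback.

## Filters and redundancy resolution

Because a small reference set estimates the scale poorly, two
reference-variability rules remove intrinsically unstable pairs before
significance is interpreted: (1) pairs whose *reference* ratios are
themselves outliers ($|M_i| > 3.5$ against the full reference median/MAD)
in three or more reference samples; (2) pairs containing a protein whose
reference log quantity falls outside
$\mathrm{median} \pm 1.4826 \times 2 \times \mathrm{MAD}$ in three or more
reference samples. When a protein's MAD is zero that band collapses to the
median, so any off-median sample counts. The threshold of three offending
samples was calibrated for a 10-sample reference set; a fractional mode
(`maxRefOutliers = "auto"`, $\lceil 0.3\,n_\mathrm{ref}\rceil$) is provided
for other sizes. Flat exclusion lists (typically GO:0005200 structural
cytoskeleton constituents, whose apparent shifts can reflect stromal
content, and GO:0003735 ribosomal proteins, which lack isoform-resolved
annotation) remove pairs by annotation. Filters run in the order
annotation → variability → significance → redundancy, and the run log
records every removal.

A single strongly dysregulated hub protein would otherwise be reported once
per interaction partner. For each significant pair, a protein *contributes*
if its own single-protein $|M_i| > 2$ (same machinery, applied to its log
quantity) in at least half of the pair's outlier samples — the lower
threshold deliberately retains pairs where both proteins moved mildly but
oppositely. "At least half" is implemented as count $\ge$ flagged/2, so 2
of 4 passes and 1 of 3 fails. Each contributing protein is then represented
by its single highest-scoring pair: pairs are visited in decreasing score
order (ties: smaller adjusted p, then lexicographic pair key) and kept only
if none of their contributors is already represented. This greedy order is
the only rule that simultaneously guarantees that no contributor appears in
two kept pairs and that a pair whose proteins contribute nowhere else is
never removed; pairs with *no* contributing protein cannot cause hub
redundancy and are kept, flagged as such. A protein with a zero reference
MAD cannot be standardized and is treated as non-contributing (logged).

## Differential correlation (corShift)

Complex assembly or disassembly between two sample groups shows up as a
gain or loss of co-expression. For every measured pair, Pearson
correlations are computed separately in the two groups over
pairwise-complete observations (no imputation; fewer than 8 paired
observations makes a group untestable, because correlation p-values below
that are fragile). Two-sided p-values use the exact-null transform
$t = r\sqrt{n-2}/\sqrt{1-r^2}$ with $n-2$ degrees of freedom and are
BH-adjusted *within each group* across all testable pairs (matching how a
per-group adjusted p accompanies each reported correlation). A pair gains
correlation in group B iff $r_B > 0.6$ and adjusted $p_B \le 0.05$, it is
*not* significantly correlated in group A by the same rule, and
$|r_B - r_A| > 0.6$; symmetrically for A. $\Delta r = r_B - r_A$ is
reported signed.

A consequence worth knowing: for a true correlation of 0.8 in an 18-sample
group, the sampling distribution of $r$ (Fisher z scale, sd
$1/\sqrt{15}$) puts only ~77% of draws above the joint
$r > 0.6$ **and** $\Delta r > 0.6$ requirement even before the adjusted-p
condition, so the classifier's sensitivity at that effect size and sample
size is intrinsically capped near three-quarters. The thresholds favor
precision — a classified gain is a strong claim — over recall.

## Complex-level analyses

Complex over-representation among significant proteins uses a two-sided
Fisher's exact test per complex (2×2: membership × significance, over the
analyzed background), BH-adjusted across complexes. Whole-complex
regulation is scanned on a median-subunit trace: subunits measured in more
than half of all samples are kept (strictly >50%, configurable), the
complex value in a sample is the median over kept subunits and exists only
where *all* kept subunits are measured, complexes with fewer than two kept
subunits are dropped, and the modified z machinery runs on the trace. A
complex is retained when it is an outlier in at least 10% of the
*evaluable* test samples (inclusive bound); because evaluability varies,
the fraction over all test samples is reported alongside. The regulation
direction is the sign of the mean outlier $M_i$ — the natural summary, as
no finer rule is standard.

# The synthetic-data generator

`simulatePQRData()` emulates the statistical structure the screen assumes:
per-protein baselines drawn once from $N(20, 2)$ log2 units (typical MS
dynamic range), shared per-sample latent factors within each complex
(weight 0.25 by default, i.e. within-complex co-expression $r \approx 0.5$
— note the shared factor cancels in within-complex ratios, exactly as
complex co-regulation stabilizes real PQRs), independent $N(0, 0.25)$
measurement noise, and missingness completely at random (2% by default).
Default cohort geometry is 10 reference and 24 test samples, a typical
cell-line panel split. Ground-truth events are injected on top:

* **PQR shifts** — a log2 delta added to one protein of a pair in a random
  fraction of test samples (optionally split oppositely across both
  proteins, the mild-but-opposite case the contribution test protects);
* **correlation gains** — a new shared latent factor for both proteins in
  one group only, giving within-group correlation
  $w^2/(w^2 + \sigma^2)$;
* **hub shifts** — one protein shifted in all test samples.

What it does *not* emulate: peptide-level noise, batch effects,
intensity-dependent missingness, or heavy-tailed biological variability.
Tests passing on this generator therefore demonstrate the statistical
machinery under the model's own assumptions, not robustness to real MS
artifacts.

# Numerical choices and degenerate inputs

* Log base: inputs are expected in log2; raw intensities can be
  transformed on read (`alreadyLog = FALSE`), non-positive raw values
  become missing. All deltas and MADs are in log2 units.
* Median of an even count: arithmetic mean of the two central values
  (R's convention).
* Pairs are unordered; ratio orientation is fixed alphabetically so
  outputs are deterministic. Anti-symmetry (swapping orientation negates
  every $M_i$) is a tested invariant.
* A pair with fewer than 5 non-missing reference ratios (configurable) or
  a zero reference MAD is untestable — an epsilon in the denominator would
  manufacture unbounded scores, so none is used; counts are logged.
* Background size defaults to $\max(1000, 10 \times$ testable pairs$)$,
  enough to estimate the gamma tail beyond the real score range; at least
  200 pairs are required outright. The seed is mandatory and echoed in
  every run log.
* Samples assigned to neither `reference` nor `test` (e.g. healthy-tissue
  controls carried in a cohort design) are ignored by the screen; finer
  `subtype` labels can name the two groups in `corShift()`.

# Known limitations

* **Reference-scale instability.** With 10 reference samples the raw MAD
  has a heavy lower tail: a pair whose reference ratios happen to cluster
  tightly gets an underestimated scale and inflated test scores. The
  pair-level variability rule removes the extreme cases; the rest are the
  price of a 10-sample reference, and the top-1% advisory flag
  plus manual inspection of outlier counts are the practical guards. With
  ~1000 null pairs, a handful of such chance pairs can rival genuinely
  shifted pairs in score, so rank lists at small reference sizes should be
  read with this in mind.
* **Protein-level band false removals.** The median ± 1.4826·2·MAD band
  with a 3-sample trigger removes a non-negligible share of perfectly
  well-behaved proteins at $n_\mathrm{ref} = 10$; the filter trades
  sensitivity for robustness to noisy references and can be disabled
  (`variabilityFilter = FALSE`) or set to fractional mode.
* **corShift sensitivity** is capped at moderate effect sizes (previous
  section).
* No imputation anywhere; missing values simply reduce the usable sample
  count per pair.

# Problem sizes used by the test suite

The packaged checks run at desk scale, chosen to finish in minutes while
keeping the statistics meaningful: null calibration uses 50 replicates of
1,000 within-complex pairs (10 reference / 24 test samples, 2,000
background pairs); shift recovery hides 10 injected pairs among 990 null
pairs; the correlation-gain power check runs 500 replicates of 5 gain
pairs among 200 null pairs at the 23-versus-18 sample geometry; oracle
comparisons (brute-force modified z, step-up BH, hypergeometric
enumeration) use exhaustive small cases.
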