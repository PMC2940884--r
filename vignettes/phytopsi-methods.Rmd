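---
title: "Ratio-matrix similarity scoring of botanical fingerprints"
author: "phytopsi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ratio-matrix similarity scoring of botanical fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytopsi)
```

## The problem

A botanical extract is a mixture of hundreds of phytochemicals, and two
batches that agree on a handful of marker compounds can still differ
materially in composition or biological activity. `phytopsi` scores whole
*patterns* instead of individual markers, on two complementary readouts:

* a **chemical fingerprint** — the fixed set of quantifiable LC/MS peaks
  (feature id, m/z in amu, retention time in minutes, integrated ion-count
  intensity) selected to characterise a batch; and
* a **bioresponse fingerprint** — a panel of signature genes whose
  expression change in a detector cell line (signed fold change versus an
  untreated control) characterises the batch's integrated biological
  activity.

Both readouts reduce to the same mathematical object: a vector of $N$
strictly positive values attached to shared feature identities, compared
between a candidate batch and a reference batch.

## The PSI statistic

Let $a = (a_1,\dots,a_N)$ and $b = (b_1,\dots,b_N)$ be the matched positive
intensity vectors of batches A and B. The conventional similarity is the
plain correlation $R = \mathrm{cor}(a, b)$. Its weakness for fingerprints
is structural: with intensities spanning several decades, $R$ is carried
almost entirely by the few largest peaks, so distortions among the minor
constituents barely move it.

The Phytomics Similarity Index (PSI) instead expands each vector into the
$N \times N$ **ratio matrix** $M$ with $M_{ij} = a_i / a_j$ for $i \neq j$
(the measured values sit on the diagonal; $M_{ij} M_{ji} = 1$, so
$N(N-1)/2$ ratios are independent). The *feature-$i$ ratio vector*
$x_i = (M_{ij})_{j \neq i}$ places feature $i$ in relation to every other
feature. For each $i$ the per-feature score is

$$ R_i = \mathrm{cor}\!\left(x_i^A,\; x_i^B\right), $$

with Pearson (default) or Spearman correlation, and

$$ \mathrm{PSI} = \frac{1}{N} \sum_{i=1}^{N} R_i . $$

Because $x_i^A = a_i \cdot (1/a_j)_{j\neq i}$ is a positive rescaling of
the leave-one-out reciprocal vector, each Pearson $R_i$ equals
$\mathrm{cor}(1/a_{-i},\, 1/b_{-i})$ — a closed form the test suite uses as
an independent oracle against the matrix implementation. Useful properties,
all enforced by tests:

* **Identity** — $\mathrm{PSI}(A, A) = 1$ exactly.
* **Scale invariance** — $\mathrm{PSI}(A, cA) = 1$ for any $c > 0$: ratios
  cancel a common dilution or injection-volume factor.
* **Symmetry** — unweighted PSI is exactly symmetric in its arguments.
* **Range** — every $R_i$ and the PSI lie in $[-1, 1]$; unrelated patterns
  score near 0.
* **Sensitivity** — each feature contributes $N-1$ ratios, so PSI spreads
  widely over batches whose conventional $R$ stays pinned near 1.

A note on rows versus columns: column $i$ of the ratio matrix is the
reciprocal of row $i$ up to a positive factor, so row and column scores
coincide for Spearman (both rank orders reverse) but **not** for Pearson,
where the column score reduces to $\mathrm{cor}(a_{-i}, b_{-i})$. The
package defines the statistic on rows throughout.

### Slope weights and outlier features

The per-feature regression slope $s_i$ of $x_i^B$ on $x_i^A$ measures how
far feature $i$'s relative abundance moved between batches. The weight

$$ w_i = \min(s_i,\, 1/s_i) \in [0, 1] \qquad (w_i = 0 \text{ for } s_i \le 0) $$

penalises slopes away from 1 symmetrically in either direction: identical
or commonly-scaled batches give $w_i = 1$ exactly, and a feature whose
intensity was multiplied by a factor $f$ gets $w_i \approx \min(f, 1/f)$.
The published description of the method leaves the exact weighting function
open ("slope weighting" only); $\min(s, 1/s)$ is this package's
documented choice, and **the default PSI is unweighted** — every report
records the flag. Because the directional slope is not symmetric in A and
B, the weighted PSI averages the A→B and B→A weights per feature before
renormalising, which restores exact symmetry and keeps the stored identity
`psi == sum(w * R_i) / sum(w)`.

`outlierFeatures()` flags features by the **slope-adjusted score**
$w_i R_i$, not by $R_i$ alone. This is deliberate: multiplying a single
intensity $b_k = f a_k$ rescales the whole of row $k$, so $R_k = 1$
*exactly* and the correlation can never expose the culprit — while every
other row degrades slightly (or severely, when the perturbed peak is
small). The slope weight, by contrast, drops to $\min(f, 1/f)$ for the
perturbed feature only, so $w_k R_k$ isolates it as the single low value
in the score histogram (fixed-width bins over $[-1, 1]$, 40 by default).
For globally noisy batches many features fall below the flagging threshold
together — that pattern, as opposed to one isolated low score, indicates
spread variation rather than a single discrepant constituent.

### Degenerate inputs and numerical choices

* Matched pairs require $N \ge 3$ strictly positive values; zero or
  negative intensities are rejected at construction (ratios would be
  undefined), and unmatched features are dropped with a logged count, never
  zero-imputed.
* Identical ratio vectors short-circuit to a score of exactly 1, making the
  identity property exact rather than floating-point-approximate.
* A constant ratio vector (all other intensities equal) has no defined
  correlation: the fallback score is 1 when both vectors are constant
  (equal-ranked by convention) and 0 when only one is, with a warning.
* A zero-variance regressor yields slope weight 0 with a warning.
* Invariant checks (reciprocal symmetry of ratio matrices, result validity)
  use a relative tolerance of 1e-9; oracle agreement in the test suite is
  asserted at 1e-10.

## Fingerprint construction and matching

`selectFingerprintPeaks()` builds the QC peak set from two or more
replicate injections: a peak is retained when it appears in **every**
replicate, its mean relative intensity exceeds `minRelIntensity` (default
0.002, i.e. 0.2 % of the base peak), and its across-replicate intensity CV
is at most `maxCv` (default 0.30; the upstream "reproducible integration"
rule is qualitative, so the ceiling is configurable and recorded in the
fingerprint's `selectionParams`). Retained peaks carry across-replicate
mean intensity and coordinates, ordered by retention time. The ten-fold
linearity requirement for candidate peaks is checked separately on
dilution-series data (`linearityCheck()`, Pearson r > 0.99 to pass over
0.1–20 mg/mL), since replicate tables carry no concentration axis.

`ticCoverage()` reports the fraction of total ion current carried by the
fingerprint, counting only peaks **at or above** `threshold` × base peak in
both numerator and denominator (the at-or-above convention follows the
method's worked fractions).

`matchFeatures()` prefers exact feature-id matching when the fingerprints
share a namespace; otherwise it matches greedily by the combined
normalised distance $|\Delta m/z|/\text{mzTol} + |\Delta rt|/\text{rtTol}$
(defaults 0.01 amu — generous against routine 0.002 amu mass accuracy —
and 0.5 min), each feature used at most once, distance ties resolved
toward lower m/z and logged.

One upstream ambiguity deserves note: whether fingerprint intensities
should be compared raw or as TIC fractions. PSI is indifferent (a common
factor cancels in every ratio), but conventional R is not; the package
stores and compares intensities as given, and `normalizeToBasePeak()` is
available when a relative scale is wanted.

## Gene bioresponse panels

Signed fold changes ($+f$ = f-fold up, $-f$ = f-fold down, $|f| \ge 1$)
are mapped to strictly positive expression ratios ($-f \mapsto 1/f$)
before any similarity computation, so down-regulated genes participate in
the ratio matrix like any other feature. `commonRegulatedGenes()`
intersects replicates at a fold cutoff (presets 1.5, 1.7, 2.0, 3.0),
shrinking monotonically as the cutoff rises; `buildSignaturePanel()` fixes
gene order so that `panelSimilarity()` compares like with like, erring on
any symmetric difference. Gene symbols are matched exactly; alias
resolution is out of scope. A 15-gene reference panel (14 up-regulated,
one 2.4-fold down) ships in `inst/extdata/` as a worked fixture.

## The synthetic-data generators

All validation statistics are computed on seeded synthetic data; the
generators are pure functions of a `SyntheticSpec` (a master seed expands
into independent, counter-based streams, so adding a generator never
shifts existing fixtures). They emulate:

* **Fingerprints** — `nFeatures` (default 39, the reference pattern size)
  peaks, m/z uniform over 100–1000 amu, retention time uniform over 0–65
  min, intensities log-uniform over $[10^2, 10^5]$ ion counts (the dynamic
  range a fingerprint spans, from the 0.2 % threshold to the base peak); a
  bounded-uniform law over (0.1, 100] is available.
* **Pair scenarios** (`genPair()`) — `identical`, `scaled` (one common
  factor), `noisy`, `single_outlier` (one feature × `outlierFactor`,
  default 10), `random` (independent redraws), each returning its ground
  truth.
* **Batch noise** — the default `"counting"` model scales the per-feature
  CV as $\text{noiseCv} \cdot \sqrt{I_{\max}/I_i}$ (capped at 1), with a
  base-peak CV of 3 %: integrated ion counts obey counting statistics, so
  minor constituents are intrinsically less reproducible than major ones.
  This is what lets conventional R stay tightly clustered near 1 across an
  ensemble of noisy batches while PSI spreads widely — the discrimination
  pattern observed in practice on real batch panels. A `"constant"` model
  (one CV for all peaks, used for replicate re-injections in
  `genPeakTables()`, default 3 %) is also available.
* **Replicate structure** — `genPeakTables()` adds m/z jitter (sd 0.002
  amu) and retention-time jitter (sd 0.05 min) across injections;
  `genReplicateGeneTables()` plants regulated genes (true fold ± 5 % log
  noise) over a null background (log2 ratio sd 0.1).

What the generators deliberately do **not** model: chromatographic peak
shapes, co-elution, isotopes and adducts, detector saturation,
between-vendor compositional drift, or microarray preprocessing. Passing
tests therefore certify the statistical machinery under controlled
multiplicative-noise conditions, not end-to-end behaviour on raw
instrument data.

### A sampling caveat for unrelated patterns

For two *independent* random fingerprints the per-feature Pearson scores
reduce to sample correlations of 38-point reciprocal vectors, and the
sampling floor of a mean absolute sample correlation at that length is
$\approx \sqrt{2/\pi}/\sqrt{37} \approx 0.13$ for light-tailed laws. The
package's acceptance checks compute the mean absolute PSI of 200 random
pairs at $N = 39$ and observe ≈ 0.13 accordingly; a nominal "random data
score below 0.1" should be read as the typical-value range of single
pairs, or as the behaviour of longer fingerprints ($N \gtrsim 100$), not
as a bound on the mean absolute score at $N = 39$. Signed scores centre
on 0 as expected.

## Problem sizes and reproducibility

The shipped test suite exercises: identity/scale/symmetry/permutation
properties over dozens of seeded fingerprints; oracle agreement
(brute-force loops and the reciprocal closed form) on 54 random pairs with
$N \in \{4, 10, 39\}$ at 1e-10; 200-pair random ensembles at
$N \in \{5, 20, 39\}$ for the spread-versus-size property; and an 18-batch
noisy ensemble for the PSI-versus-R discrimination property. These sizes
were chosen to make every stochastic assertion stable across seeds while
keeping the default test run quick. `scripts/acceptance.R --seed <int>
--out <path>` recomputes the headline quantities (identity PSI and the
random-pair mean absolute PSI) from scratch against the installed package.

## Known limitations

* No raw-spectrum processing (peak picking, integration, deconvolution,
  mzML ingestion): inputs are already-integrated peak tables.
* No compound identification or absolute quantitation.
* No significance calculus for PSI — the statistic is descriptive; the
  0.85 pass threshold in `compareBatches()` expresses a working
  bioequivalence expectation, not a hypothesis test.
* The slope-weighting function is this package's documented stand-in for
  an unpublished weighting; results with `weighted = TRUE` should cite it
  as such.
* Combined chemical-plus-biological composite scores are out of scope.
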