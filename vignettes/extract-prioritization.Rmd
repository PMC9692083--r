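---
title: "Scoring natural-extract libraries for structural novelty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring natural-extract libraries for structural novelty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npscout)
library(dplyr)
```

## The problem

A natural-products laboratory profiling a library of crude extracts by
untargeted LC-MS/MS faces a ranking problem: of dozens or hundreds of
extracts, which few are worth the months of isolation and structure
elucidation work? Dereplication (annotating known compounds from spectral
libraries and in-silico tools) tells you what is *already known* in each
extract; what you want to isolate is what is *not*. `npscout` condenses the
evidence into one number per extract, the **Priority Score**

$$PS = w_{FC}\,FC + w_{LC}\,LC + w_{CC}\,CC + w_{SC}\,SC,$$

an equally weighted (by default, all $w = 1$) sum of four components, each
normalised to roughly $[0, 1]$. The higher the PS, the stronger the case
that the extract holds unreported chemistry.

## The four components

### Feature Component (FC) and Feature Specificity (FS)

The aligned feature table (features $\times$ extracts, peak areas) is
normalised **row-wise**: each feature's areas are divided by its total over
the scored extracts, giving the share of that feature's signal in each
extract. A feature is *specific* to an extract when its share there reaches
`min_specificity` (default **0.90**). For each extract,

$$FS = \frac{\#\{\text{specific} \cap \text{detected}\}}{\#\{\text{detected}\}},
\qquad
FC = \frac{\#\{\text{specific} \cap \text{detected} \cap \text{unannotated}\}}{\#\{\text{detected}\}},$$

where *detected* means area $> 0$ and a feature counts as *annotated* when
any source supports it: a spectral-library hit surviving the quality gates
(|ppm error| $\le 5$, shared peaks $\ge 10$, cosine $\ge 0.6$, matching ion
mode, charge $\le 2$; all boundaries inclusive), an in-silico spectral
match with final score $\ge 0.3$, or a formula/structure prediction with
ZODIAC score $\ge 0.9$ and confidence $\ge 0.25$. The sources combine by
OR. An FC of 0.6 therefore reads: 60 % of this extract's detected features
are found essentially nowhere else in the set and have no structural
annotation. Empty extracts score $0/0 = 0$ by definition, so they rank
last rather than erroring.

**Shared specificity.** When one species contributes several extracts
(organs, collection sites), a compound genuinely specific to the species
spreads its signal over them and no single extract reaches 0.90. The
`max_occurrence` parameter $N$ relaxes this: within each species' extract
set, a feature is specific to each of its top-$\min(N, |S|)$ extracts by
share (where its share is nonzero) whenever those top shares jointly reach
`min_specificity`. With $N = 1$ this reduces exactly to the plain
threshold. The top-$N$-by-value rule is our reconstruction — it is
deterministic, order-free, and reproduces the intended behaviour that
organs of one species gain specificity as $N$ grows; since shares sum to
1, at most one species can win a feature whenever the threshold exceeds
0.5.

### Literature Component (LC)

LC is spectral-data-independent: it starts at 1 (taxon never studied) and
subtracts one weighted fraction per taxonomic rank,

$$LC = 1 - \left(w_{sp}\frac{rcs}{max_{sp}} + w_g\frac{rcg}{max_g} + w_f\frac{rcf}{max_f}\right),$$

with $rcs, rcg, rcf$ the reported-compound counts for species, genus and
family from an offline occurrence table (standing in for live
natural-product-database queries), defaults $max = 20/100/500$ and
$w = 1/3$ each. We deliberately expose every piece of this formula
(weights, maxima, and an optional per-fraction cap at 1): the exact
combination used to produce published LC values is not recoverable from
any single fixed variant, so the formula is parameterised and the package
treats LC as a configurable penalty rather than a canonical constant. By
default fractions are uncapped, so heavily studied taxa (thousands of
reported compounds) drive LC well below zero — a desirable property, since
it actively demotes them in the ranking.

### Class Component (CC)

CANOPUS-style class predictions give every feature a chemical class from
the natural-products classifier ontology (class level only) with a
probability. For each extract we keep the *recurrent, confident* classes:
probability $\ge$ `min_class_confidence` (default 0.8) and strictly more
than `min_recurrence` features in the class. A `min_recurrence` $\ge 1$ is
an absolute count; a value in $(0,1)$ — including the default 0.8 — is read
as a fraction of the extract's confidently classified features, which
honours both the "more than *n* features" framing and the printed default.
Class strings are canonicalised (trimmed, whitespace-collapsed,
case-folded) before comparison. Set subtraction against the literature
class sets then gives $CC_s = 0.5$ if any recurrent class is unreported
for the species, $CC_g = 0.5$ likewise for the genus, and
$CC = CC_s + CC_g \in \{0, 0.5, 1\}$. Recurrence is evaluated per extract.

### Similarity Component (SC)

SC compares extracts on their raw MS2 content, independent of the
alignment behind FC. Every spectrum is scaled to its base peak; fragments
with relative intensity in $[0.01, 1]$ are kept; spectra with fewer than
10 kept fragments are skipped; the kept fragment m/z values, rounded
half-away-from-zero to 2 decimals, become `peak@x.xx` words, and
precursor-minus-fragment differences within $[10, 200]$ Da become
`loss@x.xx` words. (The loss ceiling is configurable; half-away-from-zero
fixed-point labels are used because word identity must be bit-stable.)
Word counts per extract form the fingerprint matrix; every word present in
any blank injection is removed, then a Bray–Curtis dissimilarity matrix is
computed (the standard choice for count-valued profiles). Three
unsupervised detectors vote:

* **Local outlier factor** on the precomputed dissimilarities
  ($k = \min(5, n-1)$, flagged above 1.5 — values near 1 mean typical
  local density);
* **one-class SVM** (radial kernel, $\nu = 0.1$, variance-scaled
  $\gamma$), used as a *leave-one-out novelty detector*: the domain is
  learned from the other $n-1$ extracts and the held-out extract is
  flagged if it falls outside. A one-class SVM scored on its own training
  points marks $\approx \nu n$ arbitrary boundary points as outliers
  whatever the data — at library sizes of tens of extracts that is pure
  noise, so the in-sample shortcut is deliberately not used;
* **isolation forest** on the dissimilarity-matrix rows (100 trees,
  subsamples $\le 256$, anomaly score threshold 0.5, fixed seed).

$SC = 1$ if at least one detector flags the extract, else 0. The OR makes
SC a sensitive, low-specificity alarm by design.

## Intensity filters

Two optional per-extract filters let the user ask how the ranking changes
when low-abundance features are discounted; both only ever set areas to
zero and all score denominators are recomputed on the filtered table.

* **Relative-intensity filter**: each extract column is scaled by its own
  maximum and areas below `min_fraction` (default 2 %) of that maximum are
  zeroed. "Sample-wise normalisation" is implemented as max-scaling: under
  sum-scaling a 2 % cut would wipe out nearly everything in feature-rich
  extracts. This filter is idempotent — the maximum always survives.
* **Quantile filter**: per extract, areas below the `q`-quantile (linear
  interpolation, default 0.75) of its *nonzero* areas are zeroed; values at
  or above the cut survive. The quantile must be taken over nonzero areas:
  aligned tables are mostly zeros, and a zero-inclusive 0.75-quantile of a
  sparse column is 0, cutting nothing — whereas the filter is meant to
  retain roughly the top quarter of *detected* features. A consequence
  worth knowing: re-applying the quantile filter recomputes the cut on the
  survivors and removes more features, so unlike the intensity filter it
  is not idempotent. Applied sequentially (intensity then quantile), the
  retained set is never larger than under either filter alone.

## The synthetic-data generator

`fixture_spec()` / `generate_bundle()` build complete input bundles —
feature table, metadata, three annotation tables, class predictions,
occurrence table, MS2 spectra — with the per-extract FS, FC, CC and SC
known by construction:

* every scored extract detects exactly `n_features` features;
  `fraction_specific` of them are planted with their entire area in their
  home extract (share 1.0, specific under any threshold $\le 1$), the rest
  are shared with bounded uniform draws so no extract can reach a 0.9
  share of them;
* `fraction_annotated` of each extract's specific features receive a
  passing annotation, cycling through the three sources, plus
  sub-threshold decoy hits that must be filtered out;
* each extract with a planted novel class gets 5 high-confidence
  predictions of a class absent from the literature sets (ground-truth
  $CC = 1$); extracts without get none ($CC = 0$);
* the non-outlier extracts share per-spectrum core fragment sets (plus a
  couple of random fragments each), making them one spectrally homogeneous
  group, while the planted outlier draws from a disjoint m/z range on a
  shifted label grid with a shifted precursor — its peak *and* loss words
  are disjoint. Blank injections use a third vocabulary, arranged so that
  blank-word removal leaves the planted geometry intact.

One integer seed drives all randomness; identical spec + seed give
identical bundles. The generator emulates the *combinatorial* structure of
a real study at desk scale — it does not simulate chromatographic peak
shape, isotopes, adduct chemistry beyond ion-identity group labels,
retention-time drift, or realistic fragmentation; passing recovery tests
therefore demonstrates the correctness of the score arithmetic and
plumbing, not performance on real instrument data.

Test and validation runs use problem sizes of 4–10 extracts and 40–120
features per extract with ~20 spectra per extract, which exercises every
code path while keeping a full run in seconds.

## Numerical and design choices

* 0/0 ratios (empty extracts) are 0; ranking ties break by descending FC,
  then filename, so output is a deterministic permutation of the input.
* PS is computed on unrounded components; the results TSV displays scores
  rounded to 2 decimals, which is why a displayed PS can differ from the
  sum of displayed components by $\pm 0.01$–$0.03$.
* Ion-identity networks are collapsed before scoring: each group keeps the
  element-wise per-extract maximum of its members' areas, and the member
  with the greatest summed area (ties: lowest feature id) provides the
  representative id, m/z and retention time.
* Blank and QC injections are carried through the tables but excluded from
  row-wise normalisation and from every score denominator; only blanks
  (not QCs) define the removed background words.
* Absent annotation sources are treated as empty tables; a taxon missing
  from the occurrence table counts as unreported (with a warning) rather
  than erroring.
* The ppm mass-error gate uses the absolute value (error sign is
  instrument-dependent); all threshold comparisons are inclusive, matching
  their min/max naming.

## Known limitations

* The LC formula is a parameterised reconstruction; comparisons of LC
  values across studies require agreeing on weights, maxima and the cap.
* SC is binary and sensitive by construction; with very small libraries
  ($n < 5$) density estimates are unstable and the LOF neighbourhood is
  shrunk with a warning.
* Specificity is relative to the analysed set: a compound present in many
  extracts of the set scores as non-specific even if unreported.
* The MGF reader is minimal (PEPMASS, SCANS/FEATURE_ID, peak lists) and
  does not handle multi-charge annotations or embedded MS1 blocks.
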