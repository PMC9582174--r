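---
title: "Occlusion saliency and reader-agreement analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Occlusion saliency and reader-agreement analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(obsm)
```

## The problem

When an AI tool flags a lung-screening CT as malignant, an occlusion-based
saliency map (OBSM) shows *where* the model looked: regions of the volume are
masked one patch at a time, and the drop in the malignancy score is recorded
as that region's importance. Radiologists are then shown the highlighted
region and asked to describe it in ordinary reporting vocabulary. Two
questions follow: do readers even agree on what the highlighted structure
*is* (a nodule? a vessel? a rib?), and do the descriptors they choose
(spiculated, calcified, solid, ...) carry information about whether the AI's
call was right?

This package implements the full analysis chain for such a study — saliency
generation, free-text normalisation, spatial clustering of rectangle
annotations, per-region topic tables, agreement summaries and nonparametric
group comparisons — together with a synthetic phantom-and-reader-study
generator, because real multi-reader annotation data of this kind are rarely
shareable.

## Occlusion-based saliency

### Model

A scorer is any deterministic function from a 3D intensity array to a
malignancy score in $[0,1]$. For a volume $V$ and a patch anchored at grid
position $g$ (origin $o(g) = g \cdot \text{stride}$, half-open extent
$[o, o + \text{patch})$, 0-based), the saliency value is

$$S(g) \;=\; s(V) - s\big(V \oslash g\big),$$

where $V \oslash g$ is $V$ with the patch voxels replaced by a fill value.
Positive $S(g)$ means the region supported the malignancy score; on the
overlay it renders towards red. The grid has
$\lfloor (n - p)/\delta \rfloor + 1$ cells per axis, so a
$128^3$ volume occluded with a $4^3$ patch at stride 4 yields a $32^3$ map
and exactly $32^3 + 1 = 32{,}769$ scorer evaluations.

### Parameters and defaults

* **patch = stride = 4 voxels per axis.** Non-overlapping $4^3$ blocks are
  the conventional resolution/cost compromise for $128^3$ screening volumes;
  both are per-axis configurable.
* **fill_mode = "volume_mean".** What to write into the occluded patch is a
  genuinely open choice; the global mean is the usual "neutral" perturbation.
  `"constant"` (e.g. air) and `"local_mean"` are selectable, and because the
  fill is configuration rather than inferred intent, fidelity of any choice
  is testable.
* **sign = "drop"** stores $s(V) - s(V\oslash g)$ so that red = supports
  malignancy, matching the blue-to-red "low to high probability of
  abnormality" reading given to readers; `"signed"` stores the raw change
  for diagnostics.
* **Truncated grids.** When $n - p$ is not a multiple of the stride, the
  trailing voxels are simply not covered (no partial windows); the package
  logs a message. The alternative — partial boundary windows — would break
  the closed-form grid-shape relation.
* **Upsampling.** `"trilinear"` (default for display) interpolates between
  grid-cell centres with constant extrapolation beyond the outermost
  centres; `"nearest"` is exact-value-preserving and is what all exactness
  tests use, with ties broken towards the lower index.
* **Peak slice and crop.** The axial slice containing the global saliency
  maximum is selected (ties towards the lowest index; a constant map returns
  slice 0 with a warning), and the displayed region of interest is the
  bounding box of pixels above a per-slice saliency quantile (default 0.95),
  padded and clipped. Per-slice min–max normalisation drives the colour
  ramp; degenerate constant slices render all-blue rather than dividing by
  zero.

### Numerical design

The occlusion loop mutates a single working copy of the volume in place
(save patch, fill, score, restore), so cost per cell is the scorer call plus
$O(\text{patch})$ work rather than a full-volume copy. This is why the
scorer contract takes a plain 3D array. The closed-form `toy_scorer` —
logistic in the mean intensity over a ground-truth nodule mask — makes every
saliency cell analytically predictable: patches disjoint from the mask have
*exactly* zero saliency, and overlapping patches match the logistic
difference to $10^{-9}$, which the test suite checks cell by cell.

## Text normalisation and topics

Annotation free text passes four deterministic stages: tokenize (lowercase;
slashes/hyphens split; digit–letter and comparison signs separated, so
"<5mm" becomes "< 5 mm"), spell-correct, remove stop words, lemmatize.

* **Spell correction** is a minimum-Levenshtein search over an explicit,
  shipped radiology word list, with maximum edit distance 1 by default
  (configurable); ties go to the earlier dictionary entry, tokens with
  digits or fewer than three characters are never corrected, and unknown
  tokens with no close entry pass through unchanged. An explicit dictionary
  was chosen over any tool-internal one for reproducibility.
* **Lemmatization** is dictionary-form suffix stripping (plural rules
  validated against the dictionary) without part-of-speech disambiguation —
  annotation fragments rarely parse as sentences.
* The pipeline is **idempotent**: re-normalising its own joined output is a
  no-op, which the suite property-tests on generator output with typos.

Topics are the fourteen descriptor families of the screening lexicon — six
associated with a lower likelihood of malignancy (solid, single, small,
benign, circumscribed, calcified granuloma/calcification) and eight with a
higher likelihood (adenocarcinoma, malignant, irregular/ill-defined,
satellite/spiculated, consolidation, indeterminate, lobulated,
non-specific). Synonym surface forms ("tiny" and "< 5 mm" both mean
*small*) are stored normalised; multi-word phrases are matched on the joined
lemma string before single tokens, and the loader enforces that every
surface form maps to exactly one topic. An annotation may mention several
topics (a presence vector, not a single class). The shipped synonym table is
a reconstruction from the fourteen descriptor families, not any study's
internal merge list, and users can extend the YAML.

The high-level **main label** uses a small taxonomy — nodule,
vessel/vein/artery, diaphragm/rib, opacity, other — resolved in that
priority order (an annotation mentioning both "nodule" and "vein" is a
nodule annotation); no keyword match yields `"unlabeled"`.

## Spatial clustering of annotation anchors

Readers outline rectangles; the upper-left corner is the first point they
click and is used as the cluster anchor. Within a case, points are processed
in a deterministic order (sorted by reader, then row) and each point joins
the existing cluster whose **geometric median** is nearest if that distance
is strictly below the threshold (default 50 px, in display-pixel units — no
millimetre conversion), otherwise it founds a new cluster; the joined
cluster's median is recomputed after every addition. The processing order is
fixed for determinism; an option randomises it under a seed so order
sensitivity can be measured rather than guessed. Single linkage
(`cluster_single_linkage`) ships as the comparison rule: on well-separated
ROIs the two agree, and the suite asserts equality of cluster counts across
50 simulated studies.

The **threshold sweep** (10–100 px, step 10) re-runs the clustering per
threshold; on the default synthetic studies counts decrease up to 50 px and
plateau after it, which is what motivates the 50 px default. Monotonicity is
asserted empirically on the benchmark suite, not claimed as a theorem — the
sequential rule is not in general monotone in the threshold.

Because readers could annotate either the original image or the saliency
overlay (same pixel frame, identity registration), per-variant clusters are
then **merged**: clusters whose medians fall within the merge threshold are
unioned transitively (union–find over the input medians) and each merged
cluster's median is recomputed from the pooled anchors. The closure is taken
over the *input* medians deliberately: recomputing medians between merges
can pull a merged cluster away from a neighbour it should absorb.

### Weiszfeld details

One point returns itself; two points return the midpoint (every point of
the segment minimises the distance sum, so the midpoint is the canonical
deterministic choice). Otherwise Weiszfeld's iteration runs from the
centroid with an $\varepsilon = 10^{-9}$ guard against iterates coinciding
with a data point, displacement tolerance $10^{-6}$, and at most 1000
iterations. Weiszfeld's linear rate collapses in two realistic situations —
minimizer adjacent to a data point, and near-collinear anchors producing a
flat valley — so on non-convergence the iterate is polished with BFGS on
the smooth objective (analytic gradient, result clamped to the bounding
box). The suite checks the result against an iteratively refined grid-search
oracle to $10^{-3}$, including the equilateral-triangle Fermat point and a
near-singular five-point fixture.

## Agreement and group comparisons

For every cluster the package reports the modal main label, the **modal
fraction** (share of labeled members bearing it) and a **unanimity flag**;
the overall unanimity rate is the share of clusters on which every labeled
annotation used the same main label, also printed as a rounded percentage
(5 unanimous areas among 41 is 12%). Published reader studies quote
"agreement rates" under varying, often unstated definitions; this package
therefore always reports both the unanimity rate and the mean modal
fraction, explicitly labeled, and leaves any particular published rate
untargeted. Clusters whose members are all unlabeled are excluded from the
denominator and logged.

Per-ROI **topic percentage tables** cover the clusters annotated as nodule
by at least one reader: each cell is the percentage of the ROI's annotations
mentioning the topic, computed at full precision and rounded to integers
only for display.

Group comparisons use the **Mann–Whitney U test** on per-ROI percentages.
The statistic comes from rank sums with midranks for ties; the two-sided
p-value is exact (complete enumeration) when the combined sample size is at
most 16 with no ties, and otherwise the normal approximation with tie and
continuity correction. Exact-regime p-values are verified bit-for-bit
against an exhaustive enumeration oracle for all sample sizes with
$n_a + n_b \le 12$. The five preconfigured contrasts compare correctly and
incorrectly classified cases within each truth group (cB vs mB, cM vs mM),
benign vs malignant overall, and the two contrasts that share an AI output
(cB vs mM both called benign; mB vs cM both called malignant). Group means
are unweighted over ROIs by default, with an annotation-weighted option,
since per-area weighting is itself a reporting choice. P-values are reported
raw — multiple-descriptor testing is left unadjusted to match standard
reporting of such tables — with an off-by-default Benjamini–Hochberg column.
All tests are two-sided.

## The synthetic study generator

`generate_study()` simulates the observable tables of a 20-case, 36-reader
study: 10 benign cases of which 3 are misclassified by the simulated AI as
malignant, and 10 malignant of which 2 are misclassified as benign (so the
derived groups are cB=7, mB=3, cM=8, mM=2). Cases carry one to three true
ROIs at fixed anchors at least 220 px apart on a 512×512 display — 17 ROIs
on the benign cases and 24 on the malignant, of which 14 and 20 are nodules,
the remainder vessels or diaphragm/rib structures. Each reader annotates
each true ROI independently with probability 0.7 (giving roughly a thousand
annotations), with:

* anchor jitter: isotropic Gaussian, default σ = 5 px — small against the
  220 px separation and the 50 px threshold, so the true clustering is
  recoverable, which is exactly what makes recovery a meaningful test;
* text: the expressed main-label keyword plus per-topic Bernoulli mentions
  with group-dependent probabilities (lower-likelihood descriptors commoner
  on benign-truth ROIs, higher-likelihood ones on malignant-truth ROIs, and
  misclassified-benign ROIs leaning towards malignant vocabulary — a
  directional shape only, not any published table's values);
* noise: stop words injected at rate 0.3 and single-character typos at rate
  0.05 per token, the latter at edit distance 1 so that the spell
  corrector's contract is exercised end to end;
* optional label confusion (`label_confusion_rate`, default 0): readers
  occasionally describe an ROI with a different high-level label, which is
  the only mechanism by which synthetic readers disagree on the main label.

Everything is deterministic under the spec seed, and the ground truth
(per-annotation topic draws, expressed labels, ROI memberships) is returned
for recovery tests. The recovery ladder is: noiseless settings give exact
recovery of clusters, labels and topic vectors; the default jitter is still
exactly recoverable; extreme jitter (σ = 40) fragments clusters. One
finding worth stating plainly: because typos are distance-1 edits and the
shipped dictionary is well separated, the distance-1 corrector repairs
essentially all of them — recovery stays near 100% even at high typo rates,
and the suite instead demonstrates the corrector's contribution by switching
it off.

### What the generator does not emulate

No CT texture, dose or reconstruction physics (phantoms are Gaussian noise
plus smooth, optionally spiculated, spheres); no reader expertise, fatigue
or case-difficulty covariates; no negation or qualification in the text
("no nodule" mentions the topic *nodule*); readers' topic choices are
independent Bernoulli draws, whereas real descriptors co-occur. Passing
recovery tests therefore shows the pipeline is correct under its stated
noise model — not that it would extract clinically faithful topic tables
from real reports, where negation handling alone would need real NLP.

## Problem sizes used by the test suite

The suite runs the full $128^3$ occlusion grid once (32,769 toy-scorer
evaluations, about a second with the in-place loop), the cell-exact analytic
check on a $64^3$ phantom, clustering recovery and threshold sweeps over 50
simulated studies, a 1000-replicate null calibration of the Mann–Whitney
type-I error (accepted band 2–9% at α = 0.05) and a 100-replicate power
check at mention probabilities 0.5 vs 0.05 with six ROIs per group. These
sizes keep the default run near two minutes while still exercising every
stage at the study's own scale.

## Known limitations

* The sequential clustering rule is order-dependent in principle; the
  default order is fixed and an option measures the sensitivity, but no
  claim is made that the rule is order-free.
* The cluster-count plateau above 50 px is a property of the simulated (and
  presumably the original) data, not an invariant of the algorithm.
* Agreement rates beyond unanimity and modal fraction (e.g. chance-corrected
  kappa-family statistics) are out of scope.
* The saliency stage assumes the scorer is cheap enough to call once per
  grid cell; there is no batching or GPU path.
* Volumes are treated in voxel space; no registration of real CT series and
  no DICOM ingestion.
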