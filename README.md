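# obsm — occlusion saliency maps and multi-reader annotation agreement

`obsm` is an R package for a recurring question in AI-assisted lung-cancer
screening: when an AI tool highlights the image region behind its malignancy
call, do radiologists agree on what that region *is*, and do their
descriptors carry a signal about whether the AI was right?

It provides, as one tested pipeline:

* **Occlusion-based saliency maps (OBSMs)** for volumetric images against a
  pluggable scorer (any deterministic `function(3D array) -> score in [0,1]`).
  A patch slides over the volume on a regular grid; each cell stores the
  score drop `S(g) = s(V) − s(V ⊘ g)` caused by masking that patch, so a
  128³ volume with a 4³ patch at stride 4 yields a 32³ map
  (`⌊(n − p)/δ⌋ + 1` cells per axis). Maps are upsampled (trilinear or
  nearest) to native resolution, the peak axial slice is selected, and
  blue-to-red overlays and ROI crops are rendered.
* **Annotation text analysis**: tokenize → spell-correct (edit distance 1
  against a shipped radiology dictionary) → stop-word removal →
  lemmatization, then mapping to a 14-topic descriptor lexicon (6 topics
  suggesting lower malignancy likelihood, 8 suggesting higher) and a
  high-level main label (nodule > vessel > diaphragm/rib > opacity > other).
* **Spatial clustering** of rectangle anchors (upper-left corners) by
  sequential geometric-median growth with a strict 50 px threshold,
  Weiszfeld iteration with a quasi-Newton polish, threshold sweeps
  (10–100 px) and cross-variant cluster merging; single linkage ships as the
  comparison rule.
* **Agreement statistics**: per-ROI modal main label, modal fraction and
  unanimity rate; per-ROI topic percentage tables over nodule-labeled
  clusters; Mann–Whitney U comparisons (exact by enumeration in the
  tie-free small-sample regime, normal approximation with tie and
  continuity correction otherwise) between case groups — cB/mB/cM/mM for
  correctly/misclassified × benign/malignant.
* **A synthetic study generator**: phantom volumes with ground-truth nodule
  masks, a closed-form logistic `toy_scorer` whose saliency is analytically
  predictable, and simulated 36-reader annotation studies (10 benign cases,
  3 misclassified; 10 malignant, 2 misclassified; ~1000 annotations with
  jittered anchors, topic mentions, stop words and typos) with full ground
  truth for recovery testing.

File interfaces: NIfTI volumes and saliency maps (with a JSON sidecar), CSV
annotation/cluster/comparison tables (RFC 4180), YAML lexicon, JSON
agreement summaries and run manifests, PNG overlays. A thin command-line
wrapper lives at `inst/scripts/obsm_run.R`.

## Worked example

```r
library(obsm)

# a synthetic reader study at the study's published scale
study <- generate_study(study_spec(seed = 7))
study
#> synthetic reader study: 1029 annotations, 20 cases (cB=7 cM=8 mB=3 mM=2),
#> 41 true ROIs, 36 readers, seed 7

# occlusion saliency on a phantom against the closed-form nodule scorer
ph <- generate_phantom(phantom_spec(
  shape = 128, nodules = list(list(center = c(64, 64, 70), radius = 6,
                                   intensity = 1)), seed = 7))
map <- compute_occlusion_map(ph$volume, toy_scorer(ph$mask),
                             occlusion_config(patch = 4, stride = 4))
map
#> occlusion saliency map: grid 32x32x32 from source 128x128x128 (base score 0.9577)
#> occlusion config: patch 4x4x4, stride 4x4x4, fill volume_mean, sign drop

up <- upsample_map(map, "trilinear")
select_peak_slice(up)          # 0-based axial slice of the saliency maximum
#> [1] 70
extract_roi_crop(up, 70, 0.99, margin = 4)
#>  x  y  w  h
#> 54 54 22 22

# the full annotation analysis: topics, clustering, agreement, comparisons
res <- run_full_study(study$annotations, study$cases,
                      out_dir = "results/run1", seed = 7)
res
#> pipeline results: 1029 annotations in 41 clusters across 20 cases; 34 nodule ROIs profiled
#> main-label agreement: 41 of 41 ROIs unanimous (100%); mean modal fraction 1.00

subset(res$comparisons, comparison == "B_vs_M" &
         topic %in% c("solid", "benign", "malignant", "spiculated"))
#>    comparison      topic n_a n_b    mean_a   mean_b     U            p               method
#> 29     B_vs_M      solid  14  20 30.924596 11.18105 261.0 2.465764e-05 normal_tie_corrected
#> 32     B_vs_M     benign  14  20  9.514345  2.77408 211.5 1.053265e-02 normal_tie_corrected
#> 36     B_vs_M  malignant  14  20  1.893599 14.61680   6.0 2.546818e-06 normal_tie_corrected
#> 38     B_vs_M spiculated  14  20  2.958597 13.45327  18.0 1.918212e-05 normal_tie_corrected
```

Reading the output: the peak slice (70) and crop sit on the planted nodule;
the pipeline recovers all 41 simulated regions of interest; unanimity is
100% because synthetic readers echo the true label by default (raise
`label_confusion_rate` in `study_spec()` to emulate real label
disagreement); and the group comparison shows lower-likelihood descriptors
("solid", "benign") used more on benign cases and higher-likelihood ones
("malignant", "spiculated") on malignant cases, with the per-ROI group mean
percentages and two-sided Mann–Whitney p-values per topic. Every run writes
six artifact CSV/JSON files plus a manifest with MD5 content hashes;
re-running with the same seed reproduces them byte-identically.

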