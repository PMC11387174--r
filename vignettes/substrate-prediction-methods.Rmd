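---
title: "Predicting substrates of m7G writers and readers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting substrates of m7G writers and readers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m7Gsub)
```

## The problem

Internal N7-methylguanosine (m7G) on mRNA is installed by the
METTL1–WDR4 methyltransferase complex and recognized by the QKI reader
isoforms QKI5, QKI6 and QKI7. Which guanine sites a given regulator
actually targets is determined experimentally by intersecting
transcriptome-wide m7G site maps with CLIP/RIP binding regions of the
regulator — an expensive assay. `m7Gsub` trains sequence-based
classifiers that, given a fixed-length RNA window centred on a candidate
guanine, score how likely that guanine is a substrate of a chosen
regulator.

The package covers the full modelling loop: feature encoding, balanced
dataset construction, model training and tuning, feature/window/algorithm
selection, cross-prediction between regulators, and a synthetic benchmark
generator so that every stage is testable without any external download.

## Sequence encodings

Six encoders turn a window $s_1 s_2 \ldots s_L$ (odd $L$, centre base G)
into numeric features. All are deterministic; `N` (used for padding at
transcript ends) is zero-filled everywhere.

* **OH** — one-hot: each base becomes a 4-bit indicator in channel order
  A, C, G, U; length $4L$.
* **NAC** — dinucleotide composition: relative frequencies of the 16
  overlapping dinucleotides AA…UU; dinucleotides containing `N` are
  excluded from numerator and denominator. Overlapping counting
  (denominator $L-1$) is the field convention.
* **ANF** — accumulated nucleotide frequency: position $i$ carries the
  frequency of base $s_i$ within the prefix $s_1..s_i$ (cumulative count
  divided by $i$); length $L$.
* **PKC** — pseudo k-tuple composition, type-I form with $k=2$,
  $\lambda=2$, $w=0.1$ by default:
  $d_u = f_u / (1 + w\sum_j \theta_j)$ for the $4^k$ tuple frequencies
  and $d_{4^k+j} = w\,\theta_j / (1 + w\sum_j \theta_j)$ for the
  correlation tiers, where
  $\theta_j = \frac{1}{L-j}\sum_i (\mathrm{EIIP}(s_i) -
  \mathrm{EIIP}(s_{i+j}))^2$.
  Published descriptions of this encoder defer to external web servers
  without fixing a variant; we fix the type-I form with the EIIP
  constants as the single physicochemical property, which keeps the
  encoder self-contained on constants already used elsewhere in the
  framework. All three parameters are configurable via
  `encoder_config()`. With $\lambda=0$ PKC reduces exactly to NAC.
* **CP** — chemical properties: ring structure, functional group and
  hydrogen bonding give A = (1,1,1), C = (0,1,0), G = (1,0,0),
  U = (0,0,1); length $3L$.
* **EIIP** — electron-ion interaction pseudopotential per base:
  A = 0.1260, C = 0.1340, G = 0.0806, U = 0.1335; length $L$.

`encode_combined()` concatenates any subset in the fixed canonical order
OH, NAC, ANF, PKC, CP, EIIP, so that a feature layout is a function of
the subset alone, not of how the request was spelled. The channel order
A, C, G, U is alphabetical; no published convention forces another one.

## Dataset construction

`build_dataset()` turns transcripts plus a positive-site table into a
ready-to-train split:

1. **Negatives, 1:1.** For each transcript carrying $k$ positive sites,
   $k$ negatives are drawn uniformly without replacement from the
   transcript's other guanines. A transcript with fewer spare guanines
   contributes what it has, with a logged shortfall. A flag
   (`exclude_sites`) optionally removes guanines positive for *other*
   regulators from the candidate pool; by default "negative" means only
   "not positive for this regulator".
2. **Windows.** Length-$L$ windows centred on each site; positions
   beyond the transcript ends are padded with `N` rather than the site
   being discarded, since the encoders define `N` handling anyway.
3. **Redundancy removal.** `dedupe_greedy()` performs greedy incremental
   clustering in input order (positives first): a window is kept iff its
   ungapped identity (matching positions / $L$) to every kept window is
   below the threshold (default 0.9, the usual nucleotide-clustering
   default). For equal-length short windows, ungapped identity closely
   tracks alignment-based identity, which is why a dedicated external
   clustering binary is not required; de-redundancy runs after windowing
   because it is the window *sequences* that must be non-redundant.
4. **Split.** Stratified 80/20 with `round()` (banker's rounding) per
   class, random under the seed.

Negatives are sampled before de-redundancy and both counts are recorded
in the manifest, so the realized class balance is always inspectable.
All coordinates are 1-based and inclusive throughout the package.

## Models, metrics and tuning

`train_model()` exposes four learners behind one interface: an RBF-kernel
SVM (the primary model), random forest, binomial logistic regression and
gradient-boosted trees. Scores returned by `predict()` are monotone
probability-like values in [0, 1]; for the SVM they are a logistic squash
of the decision values, which keeps scoring deterministic (Platt-style
probability calibration inside the SVM library is internally randomized
and would make manifests irreproducible). AUROC is rank-based
(Mann–Whitney with midrank ties), checked in the tests against an
$O(n^2)$ pair-counting oracle. If logistic regression hits perfect
separation it falls back to a ridge penalty of $10^{-6}$ and notes this
in the model object.

`grid_search_svm()` scans cost $2^{-3}..2^{9}$ and gamma
$2^{-15}..2^{-3}$, exponents advancing by 2 (the libsvm-guide lattice,
7 × 7 = 49 cells; the step is configurable). Each cell is scored by
stratified 5-fold cross-validated AUROC **on the training partition**.
Tuning on the independent test set would leak information into model
selection, so cross-validation is the default even where reference
protocols appear to tune on the test set; `validation = "holdout"` and
the selection loops' `validation` arguments let a user reproduce the
laxer protocol for comparison. Grid ties resolve toward smaller cost,
then smaller gamma — the less complex model.

The classification threshold behind ACC/Sn/Sp is 0.5 by default and is
an explicit argument everywhere it matters, since published
threshold-based metrics rarely state it.

## Selection loops

* `search_feature_combos()` trains one model per non-empty encoder
  subset (63 in all) and ranks by independent-test AUROC, matching the
  protocol under which reference feature-ranking tables are produced;
  `validation = "cv"` gives the stricter variant. Ties prefer fewer
  encoders.
* `sweep_window_lengths()` rebuilds the dataset per length (21, 41, 61,
  81 by default) under the same seed so the site sets stay aligned, then
  trains and evaluates per length.
* `compare_algorithms()` tunes the SVM by grid search and runs the other
  three learners at documented defaults on the identical partitions.
* `cross_predict()` applies every regulator's model to every
  regulator's data, returning an AUROC matrix and a positive-rate matrix
  (fraction of *positive* windows called positive at the threshold; the
  positive substrate set is the natural reading of "all substrate
  sites"). Evaluation defaults to held-out test windows; `on = "full"`
  uses train + test.

## The synthetic benchmark

`synthetic_spec()` + `generate_synthetic()` emulate the one property of
real substrate data the classifier can exploit: a short recognition
motif near the modified guanine (e.g. `GxAG` for a METTL1-like writer,
`GxxG` for a QKI-like reader). Transcripts are i.i.d. draws from a
configurable background composition (uniform by default); positive sites
are near-evenly spaced guanines whose flank carries the motif at a
configurable offset, except for a `noise_rate` fraction planted without
it; `x` positions draw from the background. Negative windows may contain
the motif by chance, exactly as real background does. Defaults (50
transcripts of 1000 nt, 500 positive sites, noise 0.1) give the
500 + 500-window benchmark used by the acceptance checks.

What the generator does **not** emulate: splice structure, expression
levels, position-specific weight matrices, compositional biases around
real m7G sites, or correlated sites on one transcript. Passing the
planted-signal tests therefore shows the pipeline can recover a localized
sequence signal at realistic sizes — not that real-data performance
numbers will be reproduced, which depend on external CLIP/RIP data.

## Numerical choices and degenerate inputs

* Every stochastic step takes an explicit integer seed; manifests record
  seeds, parameters, counts and content hashes, and re-running with the
  same seed is byte-identical.
* Windows of even length, non-G centres, out-of-bounds positions, empty
  encoder sets, mixed window lengths, single-class training or test
  sets, and all-constant feature matrices are rejected with specific
  errors; a single-class *test* set still yields threshold metrics, with
  AUROC reported as `NA`.
* `T` is silently mapped to `U` on ingest (DNA-style FASTA is common);
  any other non-`ACGUN` character is an error.
* Duplicate site-table rows collapse on ingest — sequence-level
  de-redundancy downstream would remove them anyway.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data:
the headline planted-signal experiment uses 500 + 500 windows at
$L = 61$ with the full 49-cell grid search (a few minutes on one CPU);
the selection-loop checks use 100–200 window datasets at $L = 21$, which
exercise identical code paths at a fraction of the cost.

## Known limitations

* The greedy ungapped clusterer is order-dependent by construction
  (positives first, then input order), like the tool it stands in for.
* PKC variants differ across the literature; only the type-I form is
  implemented.
* No class-imbalance handling beyond the 1:1 design, no calibration
  analysis, and no structure- or genome-derived features.
* Real substrate tables (GEO CLIP/RIP intersected with m7G site
  databases) must be prepared upstream; `read_site_table()` documents
  the expected format but the package does not download or peak-call.
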