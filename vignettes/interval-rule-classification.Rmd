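---
title: "Classifying expression profiles with interval association rules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying expression profiles with interval association rules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intclass)
```

## The model

`intclass` is an associative classifier for gene-expression matrices. Its
premise is that *expression intervals*, not marginal fold changes, carry the
discriminative signal between phenotype subtypes: a gene may occupy one
range of values in one class and a different range in the other even when
the class means barely differ. The pipeline turns that premise into a
classifier in five stages:

1. **Gene screening.** Each gene is tested for a between-class difference
   and genes with `p > alpha` are dropped. The default statistic is the
   Welch two-sample *t* (unequal variances, Welch–Satterthwaite degrees of
   freedom). The screening step is deliberately pluggable: a location test
   is provably blind to mean-matched distributional differences, so a
   Kolmogorov–Smirnov alternative (`filter = "ks"`) is provided for data
   whose signal lives in shape rather than location. No multiplicity
   correction is applied by default; a Benjamini–Hochberg flag exists.
2. **Discretization.** Each kept gene's value range is partitioned into
   intervals. The default is ID3: recursive entropy-driven splitting
   supervised by the class labels, with candidate cuts at boundary
   midpoints between consecutive distinct values. Alternatives: equal-width
   binning (EWIB), a ternary up/normal/down baseline with cuts at
   `mean ± z·sd`, and a pass-through mode (`none`) giving one bin per
   distinct training value. All cut lists are wrapped into a left-open
   partition of the whole real line, `(-inf, c1], (c1, c2], …, (ck, +inf]`,
   so every unseen test value still maps to exactly one interval.
3. **Mining.** Within each class, every sample becomes a transaction of
   (gene, interval) items. Items whose interval covers fewer than
   `min_interval_size` of the class's samples are discarded, then the
   maximal frequent itemsets (support ≥ `minsup`) are mined with a
   MAFIA-style depth-first bitmap search.
4. **Rules.** Each maximal itemset becomes a candidate rule
   `antecedent → class`, with class-local support and confidence
   `P(class | antecedent)` over all training samples; candidates under
   `min_confidence` are dropped. A greedy leave-one-gene-out pass then
   removes antecedent items whose presence does not help training
   accuracy.
5. **Classification.** An unknown sample `u` is discretized under the
   training scheme and scored per class:
   `S(u, c) = (1/|R_c|) Σ_r f(u, r)`, where `f1 = m/|antecedent|` is the
   matched-item fraction and `f2 = (m/|antecedent|)²` rewards near-complete
   satisfaction. The sample goes to the class with maximal score. The two
   `f` variants are reconstructions: they honor the documented dependence
   on matched items and rule cardinality, but exact fidelity to the
   original pair of satisfaction functions is not claimed, which is why the
   variant is an explicit parameter.

For `K > 2` classes a one-versus-all wrapper trains one binary model per
class (its own filter, scheme, mining, pruning) and predicts the class with
the largest margin `S(u, k) − S(u, rest_k)`.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 0.05 | screening cutoff; conventional, since no canonical value exists |
| `minsup` | 0.4 | minimum within-class support of a mined itemset |
| `min_interval_size` | 0.05 | minimum fraction of class samples an item's interval must cover |
| `min_confidence` | 0.05 | minimum `P(class given antecedent)` of a rule |
| `min_leaf` | 2 | ID3 minimum samples per side of a cut |
| `bins` | 5 | EWIB bin count |
| `ternary_z` | 1 | ternary "normal" half-width in sd units |
| `score` | `f1` | satisfaction variant |

`minsup`, `min_interval_size` and `min_confidence` defaults are the
method's established defaults; `min_leaf = 2` prevents one-sample
intervals that the minimal-interval-size filter would discard anyway.

Two readings of "minimal interval size" are defensible — sample coverage
or geometric width. Coverage is the default (`interval_size_mode =
"coverage"`) because it is scale-free and matches the motivation of
discarding intervals that are narrow *and* weakly supported; width-based
filtering relative to the gene's training range is available behind
`interval_size_mode = "width"`.

## Numerical and procedural choices

* **Interval openness.** Intervals are `(lo, hi]`. Some convention is
  needed for values equal to a cut; left-open/right-closed makes "the
  unique interval containing the value" literally true at boundaries.
* **ID3 stopping.** A node stops when class-pure, smaller than
  `2·min_leaf`, or when no boundary cut has strictly positive gain
  (`> 1e-12` guards against floating-point noise). Gain ties break toward
  the smallest cut, making the scheme deterministic.
* **Ternary sd.** The population (1/n) standard deviation is used.
* **Frequency threshold.** Support ≥ `minsup` is implemented as a count
  threshold `ceiling(minsup·n − 1e-9)` to avoid floating-point misses at
  exact multiples.
* **Mining correctness.** The miner's contract is defined by a brute-force
  enumerator over all itemsets (the test suite checks set-equality on
  hundreds of random databases); the MAFIA-style optimizations (bitmaps,
  head-union-tail pruning, superset pruning) are performance details, and
  output is canonically ordered (size descending, then lexicographic).
* **Pruning criterion.** "Does removing this item help?" is judged by
  training-set accuracy of the fixed rule set (refitting inside the
  pruning loop would change the very rules under edit). Removals are also
  rejected if they would push a rule below `min_confidence` or duplicate
  another antecedent of the same class, so every rule-set invariant holds
  throughout. Greedy passes iterate to a fixed point, which makes pruning
  idempotent and training accuracy monotone by construction. A rule is
  never reduced below one item.
* **Tie-breaking.** Equal class scores go to the class with more training
  samples, then to the lexicographically first label. Arbitrary but
  deterministic.
* **ROC.** The decision statistic of a binary model is
  `S(u, positive) − S(u, negative)` with the positive class defaulting to
  the lexicographically last label; the curve is a threshold sweep over
  the observed statistics (ties move together) and the AUC is trapezoidal.
* **LOOCV.** The *entire* pipeline, including the gene filter, is refit
  inside every fold. Filtering outside the loop would leak the held-out
  sample into feature selection and bias accuracy upward.
* **Rule files.** Open-ended intervals are serialized as `-inf`/`+inf`
  rather than a sentinel magic number, and bounds are printed with the
  shortest decimal representation that round-trips the IEEE double, so
  write–read cycles are exact.

## What the synthetic generator emulates

`synthesize_dataset()` plants known interval structure so that every stage
of the pipeline can be exercised and checked against ground truth without
external data.

* **Noise genes** are `Normal(0, noise_sd)` in every class (optionally t
  with 3 df for heavy-tail robustness checks).
* **Shift structure** gives signature genes class means separated by
  `effect_size · noise_sd`. The class-conditional law is a truncated
  Gaussian (±1.25 sd around the class mean) rather than a full Gaussian.
  This is a deliberate design choice: it makes the advertised per-class
  generating intervals well-defined bounded sets, and for
  `effect_size ≥ 2.5` the classes are literally disjoint, so the invariant
  "every ID3 cut for a signature gene lies between the class means" holds
  by construction. An untruncated Gaussian sends occasional deep stragglers
  into the other class's range, which ID3 dutifully isolates with cuts
  outside the class-mean bracket — falsifying that invariant in roughly
  two-thirds of runs at the default sizes.
* **Band structure** (two classes) plants mean-matched, mirror-symmetric
  band pairs: with `h = effect_size · noise_sd`, class 1 draws 2/3 of its
  samples uniformly from `(h, 3h)` and 1/3 from `(-5h, -3h)`; class 2 uses
  the mirror image. Within-band draws are antithetic (mirrored pairs
  around the band center), pinning each class mean at the deterministic
  band-center average so fold-change is ≈ 0 by construction. The mirror
  symmetry means both classes cover every symmetric interval identically:
  ternary cuts at `mean ± sd` (the pooled mean is ≈ 0) split the two
  classes across up/normal/down items in the same proportions, so the
  ternary baseline extracts no class information, while the bands
  themselves are disjoint and perfectly recoverable by ID3. A naive
  "central band vs. flanking bands" construction was rejected because any
  discretizer with a cut near the band boundary — including ternary —
  separates classes with disjoint one-band supports; the mirrored two-band
  design is the construction that actually defeats symmetric-interval
  statistics.

What the generator does **not** emulate: probe-level noise, batch effects,
normalization artifacts, gene–gene correlation, class imbalance. A green
test on this generator establishes that the implementation recovers the
structure it defines — not that the method attains any particular accuracy
on real cohorts.

Because the band classes are mean-matched, the interval-versus-ternary
comparison is run with the KS gene filter on both arms; with the default
*t* filter the screening stage would (correctly, from its point of view)
discard the mean-matched signature genes before either discretizer saw
them, and the experiment would measure the filter, not the discretizers.

## A worked example

```{r example, eval = FALSE}
ds <- synthesize_dataset(n_per_class = 12, n_signature = 6, n_noise = 30,
                         effect_size = 3, seed = 9)
model <- train_model(ds$x)
predict(model, ds$x)[1:3, c("sample", "predicted", "margin")]
rep <- loocv(ds$x)
rep$accuracy
rep$auc
```

On this cleanly separable world the model reaches LOOCV accuracy 1.0 and
AUC 1.0 (the acceptance suite reproduces the same result at the full
40-samples-per-class, 500-gene scale).

## Known limitations

* Confidence uses the plain empirical fraction; no smoothing, lift or
  conviction measures.
* Greedy one-pass-to-fixed-point pruning is deterministic but not optimal;
  exhaustive antecedent-subset search is exponential and out of scope.
* The `none` discretizer on continuous data yields one-sample bins that
  the interval filter removes; it is intended for already-discrete input.
* The pass-through semantics of `none`, the pruning acceptance criterion
  and the exact `f` variants are this package's own documented readings of
  otherwise underdetermined design points.
* LOOCV retrains `n` models; at hundreds of samples with many surviving
  genes this is minutes, not seconds.
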