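---
title: "Methods: food-word expansion and energy-density prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: food-word expansion and energy-density prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foodlex)
```

## The problem

Studies of the urban food environment that mine geotagged review text need a
dictionary of food words, each tagged by how calorie-dense the food is.
Hand-curated dictionaries are small and biased toward stereotypical
"healthy"/"unhealthy" items. `foodlex` implements a pipeline that grows such
a dictionary automatically:

1. **Seed lexicon.** Food terms with known energy density (ED, kcal/g) are
   extracted from food-composition tables, normalized, merged, and
   classified under the British Nutrition Foundation (BNF) scheme
   (very low < 0.6, low < 1.5, medium ≤ 4, high > 4 kcal/g), collapsed to
   a binary class at 1.5 kcal/g (`L_ED` vs `H_ED`).
2. **Clustering.** The seed words' embedding vectors are modelled as a
   Gaussian mixture; the number of components `K` and the covariance
   family are chosen by AIC.
3. **Expansion.** New words are harvested near the fitted centroids: a
   cosine *similarity level* `s` bounds candidate retrieval, and a
   *probability level* `p` decides whether a candidate lies inside a
   component's hyperellipse.
4. **ED prediction.** A benchmark of ten classifiers, trained on the seed
   vectors, labels each discovered word `L_ED`/`H_ED`.
5. **Corpus analysis.** Both dictionaries are matched (greedy, longest
   phrase first, up to 4-word terms) against review text; per-district
   counts are compared with a percent-increase statistic and Welch
   t-tests.

## Model and assumptions

The mixture has density $f(x) = \sum_{k=1}^K \pi_k\, \mathcal N(x;\mu_k,
\Sigma_k)$ over word vectors $x \in \mathbb R^d$. Four covariance families
are supported — `full`, `tied` (one shared matrix), `diag`, `spherical` —
fitted by EM from a k-means initialization. The free-parameter count used
in $\mathrm{AIC} = 2\,m - 2\,\ell$ is $m = (K-1) + Kd + c$ with $c$ equal
to $Kd(d{+}1)/2$, $d(d{+}1)/2$, $Kd$ and $K$ respectively.

The working assumption inherited from the underlying method is that food
words with similar character (cuisine, preparation, energy density) lie
close together in the embedding space and form roughly Gaussian clusters.
Nothing in the implementation requires this to be exactly true, but the
planted-recovery guarantees quoted below only hold when it is.

### Membership at a probability level

The notion of a word lying "inside" a component at level $p$ is ambiguous,
and both readings are first class:

* **posterior** (default): component $k$ accepts $x$ iff its
  responsibility $\gamma_k(x) = \pi_k \mathcal N(x;\mu_k,\Sigma_k)/f(x)$
  is at least $p$. Raising $p$ *shrinks* the accepted set, matching the
  observed trade-off that higher probability levels discover fewer but
  cleaner words.
* **quantile**: component $k$ accepts $x$ iff the squared Mahalanobis
  distance to $\mu_k$ is at most $\chi^2_d(p)$ — the ellipsoid holding
  probability mass $p$. This is the geometric "hyperellipse" reading;
  note that raising $p$ *enlarges* the ellipsoid, so discovered sets nest
  in the opposite direction. The Monte-Carlo coverage property (a fraction
  $p$ of a component's own samples falls inside its $p$-ellipsoid) holds
  in this mode and is tested.

Because responsibilities always sum to 1 over components, a point far from
*every* cluster still has some responsibility near 1; in posterior mode it
is therefore the similarity level that rejects background vocabulary,
while in quantile mode the ellipsoid itself does. The command-line
interface requires an explicit `--mode` for this reason.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `similarity_level` | — (0.65 in examples) | cosine threshold around each centroid, in [0, 1] |
| `probability_level` | — (0.75 in examples) | membership level in (0, 1), interpretation per mode |
| `max_candidates` | 100000 | per-centroid retrieval cap before membership testing |
| `reg` | 1e-6 | ridge added to covariance diagonals |
| `max_iter`, `tol` | 100, 1e-3 | EM stop: change in mean log-likelihood per observation |
| `folds` | 5 | stratified CV folds, splits shared across all models |

The covariance ridge is essential, not cosmetic: a full-covariance
component in hundreds of dimensions fitted on a few thousand words is
singular without it. EM initialization uses `stats::kmeans` (10 restarts)
under the caller's seed, so every fit is reproducible; the log-likelihood
is non-decreasing across iterations (tested on traces).

### Classifier benchmark

The ten models (ANN, SVM, GP, AdaBoost, naive Bayes, QDA, gradient
boosting, k-NN, random forest, decision tree) run at their library
defaults first — features unscaled, matching a defaults-first benchmark
protocol (`scale = TRUE` standardizes inside each training fold). The top
five by mean CV accuracy are then grid-searched on the *same* folds:

* SVM: cost {0.1, 1, 10, 100} × RBF gamma {1/d, 1e-3, 1e-2}
* KNN: k {3, 5, 11, 21}
* RF: trees {100, 300, 600} × depth cap {none, 10, 20}
* ANN: hidden size {50, 100} × weight decay {1e-4, 1e-3}
* GP: RBF length-scale multiplier {0.5, 1, 2}

The ANN is a single-hidden-layer `nnet` network, so the grid varies width
and decay only; a two-layer configuration is out of reach for that
backend and was dropped rather than emulated. AdaBoost.M1 on depth-1
`rpart` stumps is implemented in the package itself. Class imbalance is
left unweighted by default (expanded food vocabularies are heavily
H-ED-skewed; reweighting would distort comparability with the untuned
benchmark).

## The synthetic generator

`synthetic_spec()` describes the study conditions the test-suite runs
under: `n_food_clusters = 10` isotropic Gaussian clusters
(`words_per_cluster = 50`, SD `sigma = 1`) with centers on a
radius-10 shell kept at least `min_separation = 8` SDs apart, plus
`n_background_words = 1000` background words beyond `background_offset =
30`; dimension `d = 25`. Each cluster carries an ED class, and seed ED
values are drawn strictly inside the class interval (L: 0.05–1.45,
H: 1.55–6.0 kcal/g) so a drawn value always classifies back to its class.
Word strings are opaque letter codes, so no string feature can leak labels
into matching or classification.

`d = 25` keeps full-covariance fits exercisable at desk scale while
preserving the relevant geometry (random directions nearly orthogonal,
background cosine similarity concentrated near 0); 300-dimensional spaces
work but make full-covariance grids slow. The review-corpus generator
plants Poisson term counts per outlet and always separates planted terms
by filler tokens, which is what makes *exact* count recovery by the greedy
matcher a provable property rather than a statistical one.

What the generator does **not** emulate: anisotropic or overlapping
clusters, Zipfian token frequencies, polysemy, misspellings, multiword
vocabulary entries inside the embedding itself, or annotation noise.
Passing tests therefore demonstrate correctness of the machinery under
the stated geometry, not performance on real embeddings or review
corpora.

## Numerical and procedural choices

* **AIC selection.** `calibrate()` fits every (K, family) pair and keeps
  the minimum-AIC model; a two-stage coarse→fine search
  (`refine_radius`) mirrors the usual protocol for large K ranges. At
  marginal per-cluster sample sizes AIC can prefer splitting a true
  isotropic cluster (the extra component's penalty is only
  $2(d+2)$ in the spherical family), so selected K can exceed the
  planted K on some draws; the calibration tests pin seeds and sample
  sizes where selection is determinate.
* **Percent increase.** The district statistic is the difference over the
  sum, $100\,(E-O)/(O+E)$ — the form that reproduces the published
  per-district worked examples from their count pairs; the conventional
  $100\,(E-O)/O$ is exported separately.
* **Welch t-test.** Per-outlet counts under the two dictionaries are
  compared with the unequal-variance two-sample t (fractional
  Welch–Satterthwaite df), which is what fractional dfs in the reference
  tables imply. Districts with fewer than two outlets are noted and
  skipped; identical zero-variance samples report t = 0, p = 1.
* **Greedy matching.** Longest-match-first, non-overlapping, so sub-terms
  of a matched dish name are not double-counted; an overlapping mode
  exists for sensitivity analysis. Tokenization applies exactly the
  lexicon normalization rules (lowercase, diacritics folded, any
  non-alphanumeric a separator), keeping corpus and dictionary in the
  same alphabet.
* **Ties.** Neighbor lists break similarity ties lexicographically; a
  word accepted by several components is reported under its
  highest-similarity centroid; tuned-model selection breaks accuracy
  ties by lower fold SD.
* **Degenerate inputs.** Zero vectors are rejected in cosine routines;
  empty expansion results make precision an explicit error rather than a
  silent NaN; emptied mixture components are kept well-defined by a tiny
  floor on their effective count plus the covariance ridge.

## Problem sizes in the shipped checks

The test-suite and the acceptance script run entirely on synthetic data:
mixture calibration at n = 1000, d = 25 (planted K ∈ {1, 5}); expansion
on the default 10-cluster spec (1500-word vocabulary); the classifier
benchmark on n = 2000, d = 25 with 8-SD margins (ten models, fivefold CV,
top-5 tuning), with the permuted-label chance check on an n = 500
subsample; and the end-to-end pipeline on 60 outlets across three
districts. These sizes were chosen as the smallest at which each
property is stable and meaningful.

## Known limitations

* Real pretrained embeddings (e.g. 300-dimensional news-trained vectors)
  and real composition databases are required inputs for substantive use;
  none are redistributed here, so published headline figures (cluster
  counts in the dozens, tens of thousands of discovered words, ~94%
  human-judged precision, ~92% tuned CV accuracy) are reference points,
  not reproducible outputs of this package.
* Human annotation of expansion precision is replaced by an
  export-for-annotation hook (`evaluate_precision()` without ground
  truth draws a seeded sample).
* The candidate filter excludes digit-bearing vocabulary tokens by
  default (configurable regular expression).
* Choropleth rendering of district results is out of scope; the district
  report is tabular.
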