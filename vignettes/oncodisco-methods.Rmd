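---
title: "oncodisco: models, synthetic study conditions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{oncodisco: models, synthetic study conditions, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models behind each pipeline stage,
the synthetic study conditions the package is calibrated on, the numerical
choices that matter, and what the passing test suite does — and does not —
establish about behaviour on real data.

## 1. The pipeline in statistical terms

**Stage 1 — prognostic targets.** Survival is deliberately reduced to
binary classification: a patient is labelled 1 iff their observed OS (or
PFI) time strictly exceeds the cohort median, ties going to class 0. No
time-to-event model is fitted anywhere; this mirrors the simplification
the pipeline is built around, and it is why the module's non-goals exclude
Cox-style modelling. The classifier is a single-hidden-layer perceptron
(`nnet`) on log-transformed, per-fold standardized expression. We report
out-of-fold ROC-AUC from stratified k-fold cross-validation (default
k = 5), and the mean of the fold AUCs. When synthetic rows from the
augmentation step are supplied they are appended to **training folds
only**, never scored, so the reported AUC always measures generalization
to real patients — augmenting the evaluation set as well would let the
sampler grade its own homework.

Gene importance is the absolute coefficient of an L1-penalized logistic
regression (`glmnet`), penalty chosen by cross-validation at
`lambda.min`; zero-coefficient and zero-variance genes never enter the
ranking. The OS and PFI rankings are merged by the best (minimum) rank
across the two lists, ties broken by the larger summed importance, then
lexicographically. How many genes to keep per endpoint is an explicit
parameter (`top_k`, default 25) — the original workflow reports a 36-gene
merged list without stating its cut, so no count is hard-coded here.

**Censoring.** The workflow this package emulates binarizes observed time
without mentioning censoring. The generator exposes a
`censoring_fraction` (default 0) and the binarization uses observed time
for all patients; the statistically safer option of excluding patients
censored before the median can be obtained by filtering the clinical
table before calling `binarize_outcome()`. The cohort-wide median (not a
per-fold median) is used, matching the description "the median … for the
whole dataset".

**Stage 1b — augmentation.** The tabular sampler is a per-class Gaussian
copula: each numeric column is mapped to normal scores through its
empirical CDF, a shrunk correlation matrix (weight 0.2 toward the
identity) is estimated per label class, and synthetic rows are drawn from
the multivariate normal and inverted through the empirical quantiles
(type 7). Inversion through empirical quantiles guarantees every
synthetic value lies inside the observed range of its column. A
conditional tabular GAN would fill the same contract; no R implementation
of one is available in this stack, and the copula is the deterministic,
seconds-fast default that keeps the whole suite CPU-friendly. Requesting
any other backend warns and falls back to the copula with an identical
contract.

**Stage 2 — tumor/normal filter.** The same classifier contract on
tissue labels. Importance for this stage defaults to fold-aggregated
permutation importance (mean held-out log-loss increase over 3
permutations per fold, floored at zero; log-loss rather than AUC because
it stays sensitive when the classes separate perfectly), which is
model-agnostic and reuses the CV fold models; a Lasso ranking is available behind the same interface. The
selector applied to the ranking (`top_k` or an importance threshold) is
explicit configuration, because the emulated workflow selected 4,912
genes without stating its rule. The final target list is the prognostic
list filtered to the discriminative set, *preserving prognostic order*.

**Stage 3 — literature mining.** Fully deterministic. Co-occurrence is
document-level: cell (gene, keyword) counts documents containing both
under case-insensitive whole-token matching (multi-word keywords match as
phrases), and `total_mentions` sums the keyword columns, following the
per-query article-count semantics of a PubMed-style table. Pair
extraction is same-sentence only: genes by lexicon, inhibitors by lexicon
plus token patterns (suffixes -nib/-ciclib/-parib/-zomib and 2–3-letter +
3–5-digit development codes). A fine-tuned transformer NER would slot in
behind the same interface; its reported accuracy on a hand-labelled
corpus is not reproducible without that corpus, which is why the
deterministic gazetteer is the shipped implementation.

**Stage 4 — embeddings and DPI.** A protein is read as k = 3 shifted
non-overlapping k-mer sentences (offsets 0..2, tails dropped), giving a
vocabulary inside the 8,000 possible amino-acid triplets; a compound is
read as one sentence of circular-substructure identifiers, one token per
atom per radius 0..1, where an identifier is a canonical string of
(element, degree, bond-order sum) extended by sorted neighbour
environments — stable across runs and platforms by construction. Token
vectors (d = 100) are trained by factorizing the windowed positive-PMI
co-occurrence matrix with a seeded randomized SVD; this is the classic
"skip-gram as implicit matrix factorization" view and is exactly
reproducible with one worker and a fixed seed, unlike asynchronous SGD
word2vec. The `epochs` parameter maps to power iterations of the
factorization. A protein or compound vector is the *sum* of its token
vectors; out-of-vocabulary tokens contribute zero and are counted, never
silently dropped, so the vector-sum contract is total.

Negatives for DPI training are pairs with interaction score ≤ Q1 (type-7
quantile) of the full score table, restricted to the most-scored
compounds, positives excluded. The justification is structural: in the
synthetic world (as in the emulated score database), the score range of
known positives sits strictly above Q3 + 1.5·IQR of the pooled
distribution, so the lower quartile is safely non-interacting. The 5:1
negative:positive imbalance is kept; class weighting is deliberately not
applied by default.

**Stage 5 — preclinical.** One row per sensitivity record:
log line-expression ⊕ compound vector, label = IC50 success. Driver-gene
importance is permutation importance restricted to the expression block.
Screening enforces the required target lines with a strict `>` threshold
(default 0.9) and then ranks by selectivity: ascending count of all lines
hit above threshold, ties by lower mean off-target probability, then id.
Fragments: the decomposition rule cuts acyclic single bonds that (a) have
at least one endpoint in a ring system and (b) whose removal separates
two ring-containing components. This "ring-linker" rule guarantees
idempotence — a fragment contains at most one ring system, so
decomposing it returns it unchanged. Cutting between repeated acyclic
units is not in the default rule set precisely because it would break
idempotence; the rule set is pluggable.

## 2. The synthetic study conditions

The generators' defaults are the package's declared study conditions, and
they are what the test suite and acceptance checks run on.

* **Cohort** — log-normal expression (gene-level mean log ~ N(3, 0.7),
  sd 0.8); gene `G0001` is a low-variance housekeeping reference
  (sd 0.05) used for normalization and never planted. OS and PFI times
  are exponential with log-rate `effect_size · Σ z_g / √k` over the k
  planted genes' standardized log-expression (baselines 730 / 365 days).
  `effect_size = 2` is the strong preset: at that value the median-split
  label retains a Bayes AUC near 0.92 against the linear predictor, so a
  well-fitted classifier can exceed 0.8 while the label keeps realistic
  noise from the exponential survival draw.
* **Tissue panel** — same expression family; planted genes shifted by
  `shift` (strong preset 2.0) on the log scale in tumors.
* **Molecules** — proteins and compounds carry hidden 2-dimensional
  latent vectors z ~ N(0, I). Residue frequencies (softmax tilt of a
  fixed 20×2 map), and atom/halogen/ring/double-bond frequencies of the
  valence-respecting SMILES grammar, are tilted by z, so composition is a
  noisy linear image of the latent. Sequence lengths 50–300, molecule
  sizes 10–40 heavy atoms: long enough that the latent is recoverable
  from counts, short enough to stay desk-scale.
* **Interaction world** — a pair is positive iff ⟨z_protein, z_compound⟩
  exceeds the (1 − pos_fraction) quantile of all pair dot products
  (default pos_fraction 0.1). Scores: bulk ~ Beta(2, 10), positives ~
  U(0.85, 1), which reproduces the outlier boxplot structure (positive
  minimum above the pooled upper whisker) that motivates quartile
  negative sampling. Because labels live on the latents and the model
  sees only sequence- and structure-derived features, DPI learning is a
  genuine recovery task, not a lookup.
* **Sensitivity panel** — success ~ Bernoulli(plogis(gain · s_line ·
  u_compound)) with s_line the standardized planted-driver score and
  u_compound the first latent coordinate. The default gain 12 yields a
  Bayes AUC ≈ 0.97; the interaction (product) structure makes this the
  hardest stage to learn, and the fitted model reaches ≈ 0.85–0.9, well
  above the 0.8 calibration bar but clearly below Bayes. Driver recovery
  by permutation importance is partial (typically 8–12 of 20 in the top
  40): the driver score is an exchangeable sum, so the model can reach
  high AUC from a subset of drivers, and permuting any single driver
  moves held-out AUC only slightly. The tests assert the level the
  implementation actually and robustly attains rather than an aspirational
  one.
* **Corpus** — documents of 2–5 template sentences; pair sentences plant
  an extractable (gene, inhibitor) tuple, keyword sentences plant a
  co-occurrence, filler is drawn from a vocabulary that cannot collide
  with gene names, inhibitor patterns or keywords. Ground truth is
  recorded at generation time.

What the synthetic conditions do **not** emulate: batch and platform
effects, correlated co-expression modules, real chemistry beyond
syntactic SMILES validity, censoring processes, imbalanced missingness,
or polysemous gene symbols in text. A green suite therefore shows the
machinery is correct and recovers planted signal under the declared
conditions; it does not certify performance on TCGA-like data.

## 3. Numerical choices

* Quartiles everywhere are type-7 (R default, linear interpolation),
  fixed and versioned; the quartile-negative rule is `score ≤ Q1`.
* All thresholds ("above 0.9", "over 0.99") are strict `>`. In
  `screen_library` predicted probabilities are floored at 1e-12 so a
  threshold of exactly 0 means "no filter".
* Stratified fold assignment; an impossible stratification (minority
  class smaller than the fold count) is an error, not a silent merge.
* The perceptron is `nnet` with one hidden layer (default 12 units,
  decay 0.01, 120 BFGS iterations; the preclinical stage defaults to
  16/200 because the product rule needs more capacity). Weight
  initialization is seeded per fold; single-threaded runs are exactly
  reproducible. The architecture block is configuration, not code.
* One global seed derives per-stage seeds via a stable hash of the stage
  label, so any stage can be re-run in isolation with identical results,
  and no two stages share an RNG stream.
* Ties in the merged gene list, the hit ordering, and the selectivity
  ranking all have explicit deterministic tie-breaks (documented on the
  respective functions) so reruns are digest-identical.
* Degenerate inputs: an all-equal endpoint time vector is an error; a
  zero-variance gene is dropped from rankings; a selector that passes
  zero genes warns and returns an empty set; compounds that fail to
  parse are skipped, counted and reported during screening but are hard
  errors in `compound_sentence` itself.

## 4. Problem sizes

The shipped presets are scaled for a single CPU: cohorts of 600 patients
x 120 genes (the generators handle the emulated 514 x 1,821 shape as
well), tissue panels of 600 samples, an interaction world of 50 proteins
x 250 compounds (~4,400 training pairs after quartile sampling), a
sensitivity panel of 60 lines x 72 compounds, and corpora of a few
hundred documents. A full strong-preset run takes a few minutes; all
sizes are configuration, and nothing in the code caps them.

## 5. Known limitations

* One hidden layer, BFGS, no early stopping: adequate at these sizes,
  not a modern deep-learning stack; the architecture interface is where a
  torch backend would plug in.
* The copula sampler preserves marginals and pairwise rank dependence
  only — no higher-order structure, no mode-seeking GAN behaviour.
* Substructure tokens are exact environment strings; there is no hash
  folding, so radius > 2 vocabularies can grow large on big libraries.
* Permutation importance under-ranks members of exchangeable planted
  sets (see §2); Lasso importance is sharper when effects are linear and
  sparse.
* The NER is a gazetteer: it cannot find inhibitors that match neither
  the lexicon nor the token patterns, and it does not resolve gene-name
  polysemy.
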