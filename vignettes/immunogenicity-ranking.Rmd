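---
title: "Ranking neoantigen candidates by predicted immunogenicity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking neoantigen candidates by predicted immunogenicity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neorank)
```

## The problem

Somatic missense mutations in tumors create mutant peptides. A small
minority of these, presented on HLA class I molecules, are recognized by T
cells — these are the neoantigens worth synthesizing for a personalized
vaccine or adoptive-transfer product. Binding-affinity predictors alone
rank candidates poorly because immunogenicity also depends on antigen
processing, complex stability and T-cell receptor recognition. `neorank`
implements a classification-and-prioritization stack for this problem:
curated peptide–HLA training tables in, a fused candidate ranking out.

## The model

Three submodels score each (mutant peptide, HLA allele) pair with the
probability of eliciting a T-cell response, each reading the pair through
a different encoder:

* **`fcnn_tfidf`** — the peptide and the full allele name are merged with
  an explicit separator (`"SIINFEKL|HLA-A*02:01"`), sliced into
  overlapping 6-mers (stride 1, so a string of length $L$ yields $L-5$
  tokens), and encoded as an l2-normalized TF-IDF vector with smoothed
  inverse document frequency $\ln\frac{1+N}{1+\mathrm{df}} + 1$. A dense
  network (hidden 64, ReLU, dropout 0.2, linear 2-class head) classifies
  the vector. Trained 45 epochs.
* **`cnn_embed`** — the merged string is sliced into 4-mers; each token is
  mapped to a contextual embedding; three parallel 1-D convolution
  branches of widths 3, 4 and 5 with 120 filters each (ReLU, global max
  pooling over the token axis) are concatenated, passed through dropout
  0.1 and a dense 2-class head. Trained 19 epochs.
* **`fcnn_embed`** — 2-mer token embeddings are mean-pooled to one vector
  per record and concatenated with 11 z-scored structured immunogenicity
  features; a dense network (hidden 53, ReLU, dropout 0.5) classifies the
  fused representation. Trained 31 epochs.

All three train with Adam (learning rate $10^{-4}$), batch size 32, and
softmax cross-entropy on raw logits. Class imbalance in the training fold
is corrected with SMOTE; a z-score scaler for the structured features is
fitted on the training fold only. The convolution is implemented as an
im2col matrix product over a fixed zero-padded token layout, which keeps
training on one CPU in the minutes range at $n \approx 2000$.

The three rankings are combined by a rank-level late-fusion consensus:
take the top 50 of each submodel; candidates appearing in at least two of
those lists are consensus candidates and head the fused ranking; the rest
follow by their best score across models. Two details are underdetermined
by a rank-level description and were fixed as package choices, both
config-switchable:

* ordering *within* the consensus block: support count (descending), then
  mean per-model rank, then record ID — it uses only rank-level
  information, consistent with a late-fusion design;
* ordering of the remainder: submodel scores live on different scales, so
  each model's scores are min–max normalized before taking the best
  across models (`remainder_score = "raw"` disables this).

## The contextual embedder

The embedding interface is a frozen feature extractor: the intended
production adapter is a pre-trained biomedical transformer checkpoint
(wrap it with `custom_embedder()`). The default, `hash_embedder()`, is a
deterministic stand-in that needs no checkpoint: each token is decomposed
into its character 1- to 3-grams and embedded as the mean of hash-seeded
Gaussian vectors of those pieces. The decomposition matters — a subword
tokenizer embeds similar strings similarly, and a stub that hashed whole
tokens to unrelated vectors would let the convolutional model memorize
training tokens without generalizing to near-neighbor peptides. Dimension
defaults to 64: large enough that distinct tokens stay linearly
separable in practice, small enough that the toy-scale pipeline trains in
about a minute and a half.

## Structured features

The eleven structured features are held in a registry
(`feature_registry()`) split by provenance. Scores that require external
predictors — peptide–HLA binding affinity and stability, TAP transport
efficiency, a combined CTL processing score, expression — are declared
`external_column` and joined on `(peptide, allele)`; a missing declared
column is an error, never silent imputation. The remaining six are local
proxies computed from the sequence alone: mean Kyte–Doolittle hydropathy
over the TCR-contact window (positions 4 to $L-1$, the common convention
for class-I epitopes) and over the whole peptide, a basic-residue
indicator at P1, the acidic fraction at P2–P4, aromaticity, and a
hydropathy distance to the wild-type peptide. The model layer treats all
eleven identically, so replacing a proxy with an external tool's score
changes no interface.

## The synthetic generator

`generator_spec()` emulates the composition of curated immunogenicity
training sets so every stage runs offline:

* minority positive class (default 30%);
* class-specific length mix — 9-mers 59% and 10-mers 28% among positives,
  a flatter 49%/46% split among negatives;
* positional residue structure in positives — K/R enriched at P1 and E/D
  at P2–P4 (probability 0.65 per enriched position);
* a skewed pool of 11 HLA alleles;
* eleven class-conditional Gaussian features, seven of which carry a real
  mean shift (three at 1.5 SD — the processing/presentation trio — and
  four at 0.6 SD), four pure noise;
* *motif families*: positive peptides are noisy copies (per-position
  substitution rate 0.15) of 40 length-11 consensus motifs. Curated
  databases are not i.i.d. — recurrent shared epitopes and hotspot
  mutations make immunogenic peptides cluster — and this redundancy is
  precisely what k-mer-identity encoders generalize over. Without it a
  bag-of-tokens model is at chance on held-out data by construction, for
  any training quality.

What the generator does *not* emulate: real HLA-conditional binding
motifs (anchors depend on the allele here only through the planted P1–P4
pattern), label noise from heterogeneous assays, batch effects between
source studies, and realistic feature-feature correlations. Passing
recovery tests therefore demonstrate that the estimators and training
loops work, not that comparable AUC is reachable on real curated data.

Two derived presets exist. `null_generator_spec()` removes every
class difference (no enrichment, no families, equal length mixes, zero
feature shifts) and backs the type-I calibration of the positional
chi-square tests. `strong_effect_spec()` raises the planted magnitudes
(enrichment 0.9, substitution rate 0.1, feature shifts 2.0/0.8) and is
the configuration for parameter-recovery runs: a pipeline that cannot
reach high held-out AUC under it is broken.

## Statistics

Dataset characterization follows standard practice: a chi-square test on
the 8–11 length contingency table; per-position residue-by-class
chi-square tests where residues with any expected cell below 5 are pooled
into an `other` category; per-position frequencies normalized to sum to
one per class. Positional p-values are reported raw by default (a
`p_adjust` switch is available). Feature screens report Spearman
correlations (constant features give `NA`, never silent zeros),
Shapiro–Wilk normality, Mann–Whitney class comparisons, and a 500-tree
random-forest importance ranking normalized to sum to one.

ELISpot wells are classified from background-subtracted mean spot counts
floored at zero: at least 81 spots is a strong positive, 8 up to but not
including 81 is weak (strong takes precedence at the shared boundary
count of 81), below 8 negative. Replicate outliers are removed with the
Iglewicz–Hoaglin modified z-score ($0.6745\,|x-\tilde{x}|/\mathrm{MAD} >
3.5$, with a mean-absolute-deviation fallback for zero MAD); a
deviation-from-the-mean rule was rejected because with up to five
replicates a lone outlier inflates the standard deviation it is judged
against and can never exceed 2 SD. The rule is pluggable
(`outlier_cut = Inf` disables it).

## Numerical and procedural choices

* Splits are 60/20/20, stratified by label by default (the positive class
  is small enough that unstratified test sets of a few hundred records
  are unstable); validation data is used for monitoring only — epoch
  counts are fixed per submodel, no early stopping.
* SMOTE uses k = 5 Euclidean neighbors in the exact design matrix each
  submodel trains on, balances to the majority count by default, and
  flags every synthetic row; scoring a flagged row anywhere downstream is
  an error, which is how the containment guarantee is enforced rather
  than promised.
* The z-score scaler uses the population (divisor $n$) convention so the
  fitting data itself transforms to exactly mean 0, SD 1.
* Convolution kernels are 1-D of widths 3/4/5 spanning the full embedding
  dimension (the standard text-CNN reading of multi-scale kernels), with
  global max pooling per filter.
* Degenerate inputs have defined behavior: constant feature columns scale
  to 0 with a warning; zero TF-IDF rows skip l2 normalization;
  min–max normalization of a constant score vector yields 0.5; ranking
  ties break lexicographically by record ID so all orderings are total
  and reproducible.
* Peptide/protein coordinates are 1-based with closed windows, matching
  protein mutation nomenclature; all conversions live in the enumeration
  module.
* Every stochastic step (generation, splitting, SMOTE, initialization,
  shuffling, dropout, mixing) takes an explicit seed and restores the
  caller's RNG state.

## Problem sizes

Recovery experiments run at $n = 2000$ records (1200 train / 400
validation / 400 test) with the 64-dimensional stub embedder — about 1.5
minutes per seed on one CPU. Calibration uses 200 Monte-Carlo replicates
of $n = 800$ records, which keeps the per-position expected counts high
enough for the chi-square approximation while running in under a minute.
These sizes are the package's test-scale defaults; nothing in the code
caps larger runs.

## Known limitations

* A full BioBERT-backed deployment is not reproducible offline: the stub
  embedder is not BioBERT, and no pre-trained checkpoint, curated real
  dataset or fitted weights are shipped. The architectures, preprocessing
  and fusion logic are complete; the embedder is swappable.
* The exact published definitions of the eleven structured features are
  not public in full detail; the registry's local proxies are documented
  stand-ins and external columns are first-class replacements.
* The trainer is plain R matrix algebra: adequate for tabular/toy scale
  (thousands of records), not for corpus-scale pretraining.
* The read simulator produces uniform error-free reads; it supports
  mixing-ratio arithmetic and round-trip tests, not fragmentomics or
  variant-calling realism.
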