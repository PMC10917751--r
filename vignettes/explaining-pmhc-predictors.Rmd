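---
title: "Explaining peptide-MHC class I predictors: methods and design"
author: "pepXplain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Explaining peptide-MHC class I predictors: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepXplain)
```

## The problem

MHC class I molecules present 9-mer peptides on the cell surface; whether a
peptide binds a given HLA allele is predicted by black-box models whose
outputs are probabilities in [0, 1]. A *local explanation* of one
prediction is a length-9 vector of per-position attribution values: how
much the residue at each position P1..P9 pushed the prediction toward
(positive) or away from (negative) the binding class. pepXplain computes
such explanations for any predictor exposed through its batch contract,
and — at least as importantly — quantifies whether the explanations can be
trusted, along three axes:

* **validity** — agreement with an independent per-position ground truth,
  namely alanine-scan binding free-energy differences (ddG, kJ/mol);
* **consistency** — agreement between explanations produced for two
  comparably performing predictors on the same input;
* **stability** — agreement between explanations for similar peptides
  (members of the same motif cluster) under one predictor.

## The perturbation model

All three engines share one perturbation primitive. A *coalition* is a
binary mask over the 9 positions: masked positions are replaced by the
residues of a background peptide, unmasked positions keep the original
residue. The value of a coalition S is

$$v(S) = \sum_b w_b \, f(\mathrm{splice}(x, S, b))$$

over a weighted *background set* of reference peptides. The whole masked
pattern is drawn from one background peptide at a time rather than
independently per position; this preserves residue co-occurrence in the
background and makes $v$ exactly the conditional-expectation surrogate
that Shapley analysis assumes. The background set is produced by
`summarizeBackground()`, a k-medoids (PAM) summary over Hamming distance:
medoids are actual peptides, so masked positions are always filled with
real residues (a fractional "mean peptide" has no sequence meaning).
The default of k = 25 representatives is a compromise between coalition
cost (every coalition value costs k model calls) and background fidelity.

Predictors whose raw output is a binding affinity in nM are wrapped
through `baToProbability()`, $p_{BA} = 1 - \log_{50000} BA$, clamped to
[0, 1] outside [1, 50000] nM, so the engines always explain
probabilities.

## The three engines

**Exact Shapley** (`exactShapley`) enumerates all $2^9 = 512$ coalitions
and applies the Shapley weighting
$\phi_i = \sum_{S \not\ni i} \frac{|S|!(9-|S|-1)!}{9!}[v(S\cup i)-v(S)]$.
At L = 9 this is cheap (512 × k model calls) and exact: efficiency
($\sum\phi_i = f(x) - v(\emptyset)$), symmetry and the dummy axiom hold by
construction, which the test suite verifies to 1e-9. Enumeration is
guarded to L ≤ 16.

**Kernel-SHAP** (`kernelShap`) is the regression estimator for settings
where enumeration is off the table. Proper coalitions are sampled with
replacement in proportion to the Shapley kernel
$\pi(z) = (L-1)/(\binom{L}{|z|}|z|(L-|z|))$, duplicates are aggregated by
count, and a weighted least-squares problem is solved. The kernel's
infinite weights at $|z| \in \{0, L\}$ are handled by constraint
elimination — the intercept is pinned to $v(\emptyset)$ and the last
coefficient is substituted from the efficiency constraint — rather than
by large finite weights, which keeps the normal equations well
conditioned. The evaluation budget defaults to 25,000 coalition
evaluations, the budget at which the estimator's Monte-Carlo error is
negligible at L = 9 (the suite checks max per-position error ≤ 0.02, and
an `"enumerate"` mode that evaluates each proper coalition once
reproduces exact Shapley to numerical precision).

**LIME** (`limeExplain`) draws masks with per-position keep probability
0.5, fills masked positions via the background (or uniform residues),
and fits a proximity-weighted ridge regression of the predictions on the
mask bits. Proximity is measured in the interpretable mask space as the
normalized Hamming distance D (fraction masked) with weight
$\exp(-D^2/\sigma^2)$; $\sigma$ defaults to $0.75\sqrt{L}$, a mild kernel
that downweights heavily perturbed samples without discarding them. The
ridge penalty (α = 1, intercept unpenalized) stabilizes the fit; for a
constant predictor it returns an exactly zero attribution with a
warning. The default sample budget is 25,000.

All engine randomness flows from a single per-context seed
(`explainContext(..., seed = )`); there is no hidden global RNG state,
and identical calls are bit-reproducible.

## Surrogate predictors

The package ships PSSM surrogates (`makePssmPredictor`) standing in for
trained deep-learning predictors: the peptide's summed log2-odds under a
per-allele PSSM is mapped through a logistic (default) or linear link.
Default logistic calibration maps the motif consensus to probability
0.95 and the expected background score to 0.05, so synthetic studies
contain both confident binders and confident non-binders. The linear
link maps the attainable score range onto [0.01, 0.99]; it is exactly
additive over positions, which provides closed-form Shapley values
(`perPositionLogOdds` minus the background expectation, times the
calibration slope) used throughout the tests as an analytic oracle.

## Synthetic studies and what they do (not) show

`makeSyntheticStudy()` emulates the structure of a per-allele benchmark
slice: binders sampled from a motif PSSM, non-binders from the uniform
residue background, class imbalance set by `binderFraction` (real
per-allele binder fractions are typically 1–10%, default 5%), and a
synthetic ddG profile per binder. The noise-free ddG is defined as the
additive per-position contribution of the binder under the motif,
measured against the study's own background set and scaled by
`kjPerBit` (default 3 kJ/mol per bit of log2-odds, which places strong
anchor contributions well beyond the ±4.184 kJ/mol hot/enhancing
thresholds — 4.184 kJ/mol being 1 kcal/mol). Gaussian noise of sd
`ddgNoiseSd` is added on top. Defining the ground truth this way makes
the noise-free validity correlation exactly 1 for exact Shapley on the
additive surrogate, so the validity machinery has a known fixed point;
with the logistic surrogate the link's curvature moves the correlation
slightly below 1, which is expected and documented rather than a defect.

Two things the generator deliberately does not emulate: real motifs'
residue-specific chemistry (columns are consensus-plus-uniform, not
BLOSUM-shaped), and any coupling between positions (real anchors
interact; the generator is position-independent). Passing tests
therefore demonstrate that the machinery is correct and calibrated on
position-independent data, not that any particular real predictor's
explanations are valid.

## Quality metrics

Consistency compares matched explanations from two predictors by Pearson
correlation and Euclidean distance, against a permutation baseline: the
reference explanation's values are permuted 100 times and the mean
distance to the other side is the baseline; an instance "beats the
baseline" when its actual distance is smaller. The actual and baseline
distance distributions are compared with a tie-corrected Kruskal-Wallis
test at the 5% level, pooled and per allele (the pooling choice is
reported both ways because either reading is defensible). Effect size is
epsilon-squared, $\epsilon^2 = (H - k + 1)/(n - k)$, computable from H
alone, reported alongside H and p.

Stability clusters an allele's binders with `gibbsCluster()`: Gibbs
sampling over cluster assignments where a peptide's score in a cluster
is its summed log2-odds under the cluster's pseudocounted PSSM minus
λ times that cluster's mean PSSM similarity to the other clusters
(λ = 0.05 by default — a low penalty suited to largely homogeneous
binder sets). Temperature anneals from 1.5 by ×0.9 per sweep to a floor
of 0.05; the assignment with the highest size-weighted average KLD (in
bits) over all sweeps is returned, and empty clusters are reseeded with
the worst-fitting peptide. `chooseNClusters()` scans k = 1..10 and picks
the KLD maximum. The most unrelated cluster pairs (lowest mean
column-wise Pearson correlation of log-odds PSSMs, ties broken
lexicographically) are then scored: within-cluster and cross-cluster
explanation distances, up to 100 sampled peptides per cluster, with a
Kruskal-Wallis test over the three groups (IntraclusterL, Intercluster,
IntraclusterR). No alignment moves are implemented: at fixed L = 9 the
GibbsCluster-style shift/indel machinery is unnecessary.

## Benchmarking

Per-allele AUROC uses the midrank Mann-Whitney formula; AUPRC is average
precision (step-wise, no interpolation — linear PR interpolation is
known to flatter classifiers), with ties resolved by stable input order.
Alleles with a single label class are excluded (their metrics are
undefined), mirroring the curation rule that removes such alleles. AP is
biased above prevalence at small n (about +0.04 at n = 80, +0.01 at
n = 400 in the suite's null simulations), which is why the null
calibration checks run at n = 400 per resample.

## Curation

`curateBenchmark()` applies four filters in order: fixed length (9),
removal of (peptide, allele) pairs present in any supplied training set,
removal of pairs with conflicting labels (after collapsing exact
duplicate records, first occurrence winning), and removal of alleles
left with a single class. Counts removed per filter are kept in the
result's metadata; the operation is idempotent, and conflicting-label
detection deliberately runs after duplicate collapsing so that a
repeated identical record is not miscounted as a conflict.

## Numerical choices and degenerate inputs

* Pearson correlations on constant vectors are errors (reported as
  missing), never 0: a zero would fabricate signal.
* PSSM rows must sum to 1 within 1e-9; pseudocounts (default 1,
  background-proportional) keep log-odds finite everywhere.
* KLD terms with p = 0 contribute 0; a zero background entry against
  positive probability is an error directing to pseudocounted input.
* Kernel-SHAP raises an error when the deduplicated design is singular
  (too few distinct coalitions) instead of silently regularizing.
* Allele names are canonicalized ("HLA-A*02:01" / "HLA-A02:01" /
  "HLA-A0201" all map to the starred form) before any join.
* Stage seeds derive from a global seed by a deterministic 31-bit hash
  of (seed, stage key), so pipelines are reproducible end to end; the
  demo study's reports are byte-identical across runs with one seed.

## Problem sizes

The test suite and the acceptance script run at desk scale, chosen so
the full suite completes in about a minute: synthetic studies of
300–2000 peptides, 20–50 explanation contexts per axiom check,
background sets of 6–25 peptides, Gibbs clustering of 100 peptides for
40 sweeps, 1000-resample null calibrations, and 25,000-evaluation
budgets where the stochastic engines are compared to the exact one.

## A worked example

```{r example}
motif <- motifFromConsensus("YLFPGAVKV", c(0.5, 0.95, rep(0.4, 6), 0.95))
predictor <- makePssmPredictor(motif, id = "surrogate")
background <- BackgroundSet(samplePeptidesFromPssm(
  motifFromConsensus("AAAAAAAAA", 1 / 20), 15, seed = 3))
peptide <- samplePeptidesFromPssm(motif, 1, seed = 7)
ctx <- explainContext(peptide, "HLA-A*02:01", predictor, background,
                      seed = 11)
round(attrValues(exactShapley(ctx)), 4)
```

The anchor positions (P2, P9) dominate the attribution whenever the
peptide carries the anchor residues, matching the biological expectation
that anchors drive binding.

## Known limitations

* Engines are length-generic but the toolkit targets fixed-length
  peptides; allele-sequence explanations (pseudo-sequence inputs) are
  out of scope.
* The surrogate predictors are position-independent by construction;
  they cannot probe how the engines behave under strong positional
  epistasis.
* `stabilityReport` requires explanations for the sampled cluster
  members to exist; it skips (with a warning) pairs whose clusters have
  fewer than two usable members.
* Kernel-SHAP's sampled mode aggregates duplicate coalitions by count;
  at L = 9 the 510 proper coalitions are each visited many times at the
  default budget, so its variance is far below what the same budget
  buys at larger L.
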