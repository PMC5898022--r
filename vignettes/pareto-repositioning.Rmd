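---
title: "Pareto-dominance collaborative filtering for drug repositioning: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pareto-dominance collaborative filtering for drug repositioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paretodr)
```

# The model

`paretodr` treats drug repositioning as item recommendation: a target
drug "prefers" the diseases its most similar drugs are known to treat.
The pipeline has three stages.

**Per-source similarity.** Drugs are described by several independent
binary incidence matrices — chemical substructures, protein targets,
side-effect profiles — and each source gets its own drug–drug similarity:
cosine or Jaccard/Tanimoto on the binary rows, or, when drugs carry
protein sequences, the mean pairwise Smith–Waterman local-alignment score
across the two drugs' sequence sets. The central modelling assumption is
the standard similarity-property hypothesis of chemoinformatics: drugs
that are alike in structure, targets and phenotypic effect tend to share
indications. Nothing in the pipeline mixes sources into one number at
this stage; similarities stay per-source.

**Neighbour selection by Pareto dominance.** Combining heterogeneous
similarities by weighted averaging requires weights nobody can justify.
Dominance avoids the problem: candidate $d_i$ dominates $d_j$ when it is
at least as similar to the target on every source and strictly more
similar on at least one. The non-dominated candidates are incomparable
multi-criteria optima and form the neighbour front. Iterating — peel a
front, repeat on the rest — yields as many neighbours as desired:
a single front (OD), exactly $N$ with pruning (ND), or at least $N$
without pruning (AND).

**Disease scoring.** Every disease indicated by at least one neighbour is
scored by $\mathrm{score}(c,t)=\sum_{n} \mathrm{sim}(t,n)\, f(n,c)$ with
binary $f(n,c)$ from the golden matrix; SUM drops the weight, WSUM keeps
it. The prediction list is capped at $k$ but never padded: a disease with
zero neighbour support is never emitted. This no-guessing rule is a
deliberate asymmetry — the pipeline is designed for concentrated,
high-precision shortlists that are cheap to follow up in the laboratory,
at the cost of recall.

# Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `measures` | `CCC` | per-source measure; shorthands `CCC/JJJ/JJC/JJS` map the letters to (chemical, side-effect, protein) |
| `mot` | `ND` | neighbour collection policy (`OD`/`ND`/`AND`) |
| `n` | 4 | requested neighbour count (dimensionless) |
| `ist` | `WSUM` | vote weighting (`SUM`/`WSUM`) |
| `k` | 4 | output list cap (diseases per drug) |
| `match`, `mismatch`, `gap` | 2, −1, −1 | alignment scores per residue position |
| `normalize` | `TRUE` | divide each alignment score by $\sqrt{SW(x,x)\,SW(y,y)}$ |
| `collapse` | `mean` | profile-to-scalar rule for the WSUM weight |

The alignment defaults are the simplest positive-diagonal scheme over the
20-letter amino-acid alphabet with a linear gap; any substitution scheme
can be supplied. Normalisation is on by default because dominance
compares alignment similarities against cosine/Jaccard values in the same
profile, and only the normalised form shares their $[0,1]$ scale; the raw
mean-score form remains available for users who want the literal
unnormalised statistic.

# Decisions the problem left open

Several rules are under-determined by the problem statement; the package
fixes them as follows and exposes the consequential ones in configuration.

* **Missing sources.** A drug absent from a source is distinct from a
  drug with an all-zero row. Its similarity there is *undefined* (`NA`),
  and dominance reads an undefined value as 0: absence of evidence
  confers no advantage, but also cannot veto a candidate that is strong
  on the observed sources.
* **All-zero profiles.** Candidates with no defined non-zero similarity
  are excluded before dominance; otherwise they would tie into fronts
  with no evidence at all.
* **ND pruning.** Within the final front — whose members are mutually
  incomparable by construction — pruning keeps the highest arithmetic
  mean of the defined per-source similarities, ties broken by drug name.
  Any rule here is arbitrary; this one is deterministic and favours
  all-round similarity.
* **The WSUM weight.** The method computes one similarity per source but
  the vote weight is a single scalar. The default collapse is the mean of
  the defined per-source similarities (`sum` and `max` are available).
  The mean treats sources symmetrically and does not reward having more
  sources observed, which `sum` would.
* **Zero vectors and empty alignments.** Similarity between zero rows is
  0, not an error; a local alignment with no positive-scoring pair
  scores 0. Degenerate inputs degrade gracefully instead of aborting a
  whole evaluation sweep.
* **Ties at rank k.** Prediction lists order by score, then disease name,
  and cut at `k` deterministically, so identical configurations produce
  byte-identical outputs.
* **Metric conventions.** Precision of an empty prediction list is 0 (and
  is averaged in, penalising abstention). The true-negative universe of a
  target is its own disease row, so `tn = |diseases| − tp − fp − fn` and
  specificity is per-target, then averaged. AUC-PR/AUC-ROC are likewise
  per-target over the drug's disease row (unpredicted diseases score 0),
  averaged over targets; a pooled mode that ranks all (drug, disease)
  pairs at once is available, since either universe is defensible.
* **Leave-one-out hygiene.** The target's own golden row is dropped from
  the vote source inside `predict_indications()` itself, so no caller can
  accidentally let the withheld row leak into its own prediction; a test
  corrupts the row and checks predictions are unchanged.

# The synthetic generator

`generator_spec()`/`generate_dataset()` produce the structure the method
assumes: drugs in latent clusters that share both features and
indications. Each cluster owns a per-source signature feature set and a
signature disease set, both disjoint across clusters; a drug's row is its
signature thinned by a within-cluster probability plus i.i.d. background
noise; whole drugs go missing from sources with configurable probability;
protein sequences are point-mutated copies of per-cluster ancestor
strings.

Defaults emulate a real three-source compendium at one-fifth scale: 200
drugs, 150 diseases, 176/155/277 features per source, and signature
sizes, within-probabilities and noise rates chosen in closed form (see
`expected_sparsity()`) so expected sparsities are ≈ 0.8625 (chemical),
0.9960 (protein) and 0.9503 (side-effect) — the sparsity regime of real
chemical/target/side-effect data — with about 4 indications per drug and
per-source missingness of 18/18/27 %. At one-fifth of the disease
universe the golden matrix cannot simultaneously match the ≈ 99.4 %
sparsity of a realistic indication matrix *and* the ≈ 4 indications per
drug; the per-drug indication count is kept as the anchor because it is
what drives precision@k behaviour.

What the generator deliberately does **not** emulate: real substructure
correlation (fingerprint bits are far from independent), hub drugs and
promiscuous targets, disease co-morbidity structure, synonym noise at
scale, and any mechanistic link between a sequence and the binary protein
row. Passing tests on this generator therefore demonstrate that the
algorithms are implemented correctly and behave as designed under the
assumed cluster structure — not that the method attains any particular
accuracy on real pharmacological data.

In the zero-noise limit (within-probability 1, no background, no
missingness) cluster signatures are exactly recoverable: with ND,
$N = (\text{cluster size}) - 1$ and $k$ equal to the signature disease
count, leave-one-out precision and recall are both 1. The test suite
asserts this end-to-end, and separately that with the default noise the
top-1 precision stays far above the analytic no-skill rate (the golden
density).

# Numerical and testing notes

Core algorithms are cross-checked against independent oracles rather than
spot values: non-dominated sets against a quadratic brute-force dominance
scan, local alignment against exhaustive substring enumeration with
global-alignment scoring, AUC-ROC against explicit pair counting, AUC-PR
against a threshold sweep. Dominance comparisons use exact `>=`/`>` on
doubles — similarities are ratios of small integers (or normalised
alignment scores), and candidates that should tie are bit-identical, so
no epsilon is needed.

Test and acceptance problem sizes (60–200 drugs, 60–150 diseases, up to
10 clusters) were chosen so the full suite exercises every pipeline stage,
including the alignment-based protein similarity, in well under a minute;
the pipeline itself scales comfortably to the ~10³-drug scale of real
compendia, where the alignment similarity matrix is the dominant cost and
is computed once per configuration and reused across all leave-one-out
targets.

# Known limitations

* The method is drug-sided only: no disease–disease similarity, no
  transitive inference through diseases.
* Scores are relative rankings, not calibrated probabilities.
* OD can select very few neighbours when one candidate is strong on all
  sources; the iterated policies (ND/AND) are the practical defaults.
* With pervasive ties (many identical profiles) fronts can be large, and
  ND's pruning rule, not dominance, decides the neighbour set.
* The synonym harmoniser only applies the table it is given; it performs
  no fuzzy matching or identifier normalisation.
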